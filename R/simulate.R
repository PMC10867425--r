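# Seeded synthetic-data generators with full ground truth: two-channel
# time-lapse stacks of paired kinetochore spots, variant tables with
# inbreeding-adjusted zygosity, and frame-quantized mitotic timing data.
#
# Every generator is a pure function of its configuration (seed included):
# identical configs give identical outputs.

#' Configuration for the synthetic two-channel kinetochore movie
#'
#' Defaults emulate the acquisition regimen the analysis is designed for:
#' 3 Z-planes 0.6 um apart, 6-min frame interval, ~24 diffraction-limited
#' spots (12 sister pairs) in a mitotic cell, metaphase inter-kinetochore
#' separation of 1.2 um breathing sinusoidally by 0.3 um.
#'
#' @param n_pairs number of sister pairs.
#' @param pair_separation_um baseline inter-centromere distance.
#' @param breathing_amplitude_um,breathing_period_frames sinusoidal
#'   "breathing" of pair separation: d(t) = baseline +
#'   amplitude * sin(2*pi*(t-1)/period + phase), phase random per pair.
#' @param spot_sigma_px Gaussian spot width (diffraction-limited
#'   kinetochore at 100x).
#' @param ref_spot_amplitude peak amplitude of reference-channel spots
#'   above cytoplasm.
#' @param true_ratio target kinetochore/cytoplasm ratio of the measurement
#'   channel; spot amplitudes are calibrated per spot over the analysis
#'   aperture so this value is exact in discrete arithmetic (noise-free).
#'   A vector (recycled to \code{n_frames}) imposes a time-varying ratio,
#'   e.g. a linear decay of kinetochore-bound protein.
#' @param cytoplasm_level named vector \code{c(reference=, measurement=)}.
#' @param camera_offset integer camera offset added after noise.
#' @param gaussian_sigma read-noise standard deviation; the generator's
#'   signal-to-noise ratio is \code{ref_spot_amplitude / gaussian_sigma}.
#' @param poisson apply Poisson (shot) noise to the signal before read
#'   noise.
#' @param drift_px_per_frame rigid drift of all spots, px/frame.
#' @param n_frames,n_z,img_size stack geometry (square frames).
#' @param cell_radius_px radius of the disk cell.
#' @param aperture_radius_px aperture over which the true ratio is
#'   defined; match the quantification aperture.
#' @param pixel_size_um,z_step_um,frame_interval_min physical calibration.
#' @param seed RNG seed; fixes all randomness.
#' @return list of class \code{image_sim_config}.
#' @export
image_sim_config <- function(n_pairs = 12, pair_separation_um = 1.2,
                             breathing_amplitude_um = 0.3,
                             breathing_period_frames = 10,
                             spot_sigma_px = 1.5,
                             ref_spot_amplitude = 400,
                             true_ratio = 2.0,
                             cytoplasm_level = c(reference = 30,
                                                 measurement = 200),
                             camera_offset = 100,
                             gaussian_sigma = 40, poisson = TRUE,
                             drift_px_per_frame = 0,
                             n_frames = 1, n_z = 3, img_size = 220,
                             cell_radius_px = 90,
                             aperture_radius_px = 3,
                             pixel_size_um = 0.1, z_step_um = 0.6,
                             frame_interval_min = 6, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_pairs >= 1, pair_separation_um > 0, spot_sigma_px > 0,
            all(true_ratio > 0), cell_radius_px > 0, pixel_size_um > 0,
            breathing_amplitude_um >= 0,
            breathing_amplitude_um < pair_separation_um)
  class(cfg) <- "image_sim_config"
  cfg
}

#' Simulate a two-channel kinetochore time-lapse with ground truth
#'
#' Renders a disk cell on a camera offset, isotropic 2-D Gaussian spots at
#' sister-pair positions whose separation breathes sinusoidally, Z-planes
#' with Gaussian focal attenuation, then Poisson shot noise, Gaussian read
#' noise and the integer camera offset. Measurement-channel spot
#' amplitudes are calibrated per spot so that the mean intensity over the
#' analysis aperture at the spot centre gives exactly the configured
#' kinetochore/cytoplasm ratio after background subtraction.
#'
#' @param cfg an \code{\link{image_sim_config}}.
#' @param render render pixel data (default). With \code{render = FALSE}
#'   only the ground-truth tables are produced (\code{stack} is
#'   \code{NULL}), which is much faster when only spot motion is needed,
#'   e.g. for exercising the tracker at scale.
#' @return list with \code{stack} (an \code{image_stack}) and \code{truth}:
#'   \code{spots} (per frame per spot: \code{frame, spot_id, pair_id,
#'   y_px, x_px} (0-based), \code{d_um, true_ratio}) and \code{pairs}
#'   (per frame per pair: \code{frame, pair_id, d_um}).
#' @export
sim_image_stack <- function(cfg, render = TRUE) {
  stopifnot(inherits(cfg, "image_sim_config"))
  set.seed(cfg$seed)
  H <- cfg$img_size; W <- cfg$img_size
  yy <- matrix(rep(seq_len(H), W), H, W)
  xx <- matrix(rep(seq_len(W), each = H), H, W)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  cell <- ((yy - cy)^2 + (xx - cx)^2) <= cfg$cell_radius_px^2

  # metaphase-plate layout: sister pairs lie on a grid and share a common
  # spindle-axis orientation (small per-pair jitter), as at a real
  # metaphase plate; the grid spacing guarantees a minimum inter-spot
  # separation so that sisters and neighbours remain resolvable
  sep_px <- cfg$pair_separation_um / cfg$pixel_size_um
  amp_px <- cfg$breathing_amplitude_um / cfg$pixel_size_um
  min_gap <- 4
  # neighbouring spots from other pairs stay farther away than the widest
  # sister separation, so every spot's nearest neighbour is its sister
  x_sp <- 2 * (sep_px + amp_px) + min_gap    # along the spindle axis
  y_sp <- sep_px + amp_px + min_gap          # across the plate
  nrows <- ceiling(sqrt(cfg$n_pairs))
  ncols <- ceiling(cfg$n_pairs / nrows)
  gxr <- (seq_len(ncols) - (ncols + 1) / 2) * x_sp
  gyr <- (seq_len(nrows) - (nrows + 1) / 2) * y_sp
  grid_r <- expand.grid(y = gyr, x = gxr)[seq_len(cfg$n_pairs), ]
  grid_r$y <- grid_r$y + stats::runif(cfg$n_pairs, -0.5, 0.5)
  grid_r$x <- grid_r$x + stats::runif(cfg$n_pairs, -0.5, 0.5)
  theta0 <- stats::runif(1, 0, 2 * pi)
  theta <- theta0 + stats::runif(cfg$n_pairs, -pi / 18, pi / 18)
  grid <- data.frame(
    y = cy + grid_r$x * sin(theta0) + grid_r$y * cos(theta0),
    x = cx + grid_r$x * cos(theta0) - grid_r$y * sin(theta0))
  reach <- max(sqrt(grid_r$x^2 + grid_r$y^2)) + (sep_px + amp_px) / 2 +
    4 * cfg$spot_sigma_px +
    sqrt(2) * abs(cfg$drift_px_per_frame) * (cfg$n_frames - 1)
  if (reach > cfg$cell_radius_px - 2)
    stop("sim_image_stack: spots would fall outside the cell")
  phase <- stats::runif(cfg$n_pairs, 0, 2 * pi)

  sep_um <- function(t, i)
    cfg$pair_separation_um + cfg$breathing_amplitude_um *
      sin(2 * pi * (t - 1) / cfg$breathing_period_frames + phase[i])

  ap_sel <- function(syi, sxi)
    (yy - round(syi))^2 + (xx - round(sxi))^2 <= cfg$aperture_radius_px^2
  gbar <- function(syi, sxi) {
    sel <- ap_sel(syi, sxi)
    mean(exp(-((yy[sel] - syi)^2 + (xx[sel] - sxi)^2) /
               (2 * cfg$spot_sigma_px^2)))
  }

  zc <- (cfg$n_z + 1) / 2
  z_att <- exp(-((seq_len(cfg$n_z) - zc)^2) / (2 * 1^2))

  cl <- cfg$cytoplasm_level
  if (is.null(names(cl))) names(cl) <- c("reference", "measurement")
  data <- if (render) array(0, dim = c(cfg$n_frames, cfg$n_z, 2, H, W))
  spots <- NULL; pairs <- NULL
  ratios_t <- rep_len(cfg$true_ratio, cfg$n_frames)
  for (t in seq_len(cfg$n_frames)) {
    drift <- cfg$drift_px_per_frame * (t - 1)
    sy <- sx <- numeric(2 * cfg$n_pairs)
    pid <- rep(seq_len(cfg$n_pairs), 2)
    for (i in seq_len(cfg$n_pairs)) {
      half <- sep_um(t, i) / 2 / cfg$pixel_size_um
      sy[i] <- grid$y[i] + half * sin(theta[i]) + drift
      sx[i] <- grid$x[i] + half * cos(theta[i]) + drift
      sy[i + cfg$n_pairs] <- grid$y[i] - half * sin(theta[i]) + drift
      sx[i + cfg$n_pairs] <- grid$x[i] - half * cos(theta[i]) + drift
    }
    if (any(((sy - cy)^2 + (sx - cx)^2) > (cfg$cell_radius_px - 2)^2))
      stop("sim_image_stack: spots would fall outside the cell")

    if (!render) {
      spots <- rbind(spots, data.frame(
        frame = t, spot_id = seq_along(sy), pair_id = pid,
        y_px = sy - 1, x_px = sx - 1,
        d_um = sep_um(t, pid), true_ratio = ratios_t[t]))
      pairs <- rbind(pairs, data.frame(
        frame = t, pair_id = seq_len(cfg$n_pairs),
        d_um = sep_um(t, seq_len(cfg$n_pairs))))
      next
    }

    amp_meas <- vapply(seq_along(sy), function(i)
      (ratios_t[t] - 1) * cl[["measurement"]] / gbar(sy[i], sx[i]),
      numeric(1))
    ref_sig <- cl[["reference"]] * cell
    meas_sig <- cl[["measurement"]] * cell
    w <- ceiling(6 * cfg$spot_sigma_px)        # render window, +-6 sigma
    for (i in seq_along(sy)) {
      ys <- max(1, floor(sy[i]) - w):min(H, ceiling(sy[i]) + w)
      xs <- max(1, floor(sx[i]) - w):min(W, ceiling(sx[i]) + w)
      gk <- exp(-(outer((ys - sy[i])^2, (xs - sx[i])^2, "+")) /
                  (2 * cfg$spot_sigma_px^2))
      ref_sig[ys, xs] <- ref_sig[ys, xs] + cfg$ref_spot_amplitude * gk
      meas_sig[ys, xs] <- meas_sig[ys, xs] + amp_meas[i] * gk
    }
    for (z in seq_len(cfg$n_z)) {
      for (cidx in 1:2) {
        sig <- (if (cidx == 1) ref_sig else meas_sig) * z_att[z]
        if (cfg$poisson)
          sig <- matrix(stats::rpois(length(sig), sig), H, W)
        if (cfg$gaussian_sigma > 0)
          sig <- sig + stats::rnorm(length(sig), 0, cfg$gaussian_sigma)
        data[t, z, cidx, , ] <- sig + cfg$camera_offset
      }
    }
    spots <- rbind(spots, data.frame(
      frame = t, spot_id = seq_along(sy), pair_id = pid,
      y_px = sy - 1, x_px = sx - 1,
      d_um = sep_um(t, pid), true_ratio = ratios_t[t]))
    pairs <- rbind(pairs, data.frame(
      frame = t, pair_id = seq_len(cfg$n_pairs),
      d_um = sep_um(t, seq_len(cfg$n_pairs))))
  }
  stack <- if (render)
    image_stack(data, channel_names = c("reference", "measurement"),
                reference_channel = "reference",
                measurement_channel = "measurement",
                pixel_size_um = cfg$pixel_size_um,
                z_step_um = cfg$z_step_um,
                frame_interval_min = cfg$frame_interval_min)
  list(stack = stack, truth = list(spots = spots, pairs = pairs),
       config = cfg)
}

#' Configuration for the synthetic variant-table generator
#'
#' Emulates a cohort with elevated homozygosity: genotype frequencies
#' under inbreeding coefficient F are AA: (1-q)^2 + q(1-q)F,
#' Aa: 2q(1-q)(1-F), aa: q^2 + q(1-q)F. Allele frequencies q are drawn
#' from a Beta distribution truncated to (0, 0.05] to emulate rare
#' loss-of-function variants.
#'
#' @param n_genes number of genes (the screen scale is ~135 chromosome
#'   segregation genes).
#' @param variants_per_gene variants drawn per gene.
#' @param n_individuals cohort size.
#' @param class_probs named probabilities over consequence classes
#'   \code{stop_gain, frameshift, missense, synonymous}.
#' @param inbreeding_f inbreeding coefficient F in [0, 1].
#' @param beta_shape1,beta_shape2 Beta parameters of the allele-frequency
#'   distribution before truncation at 0.05.
#' @param protein_length_range residue range for drawn variant positions.
#' @param source source-database name stamped on the records.
#' @param seed RNG seed.
#' @return list of class \code{variant_sim_config}.
#' @export
variant_sim_config <- function(n_genes = 135, variants_per_gene = 3,
                               n_individuals = 10000,
                               class_probs = c(stop_gain = 0.2,
                                               frameshift = 0.2,
                                               missense = 0.45,
                                               synonymous = 0.15),
                               inbreeding_f = 0.05,
                               beta_shape1 = 0.5, beta_shape2 = 100,
                               protein_length_range = c(300, 1500),
                               source = "SIM", seed = 1) {
  stopifnot(abs(sum(class_probs) - 1) < 1e-8,
            inbreeding_f >= 0, inbreeding_f <= 1, n_individuals > 0)
  cfg <- as.list(environment())
  class(cfg) <- "variant_sim_config"
  cfg
}

#' Simulate a variant table with CIVa ground truth
#'
#' @param cfg a \code{\link{variant_sim_config}}.
#' @return list with \code{records} (long-form variant table: \code{gene,
#'   hgvs_p, source, het, hom, q_true}) and \code{truth} (per variant:
#'   the drawn class, allele frequency and the CIVa flag, i.e. truncating
#'   and carried by >= 2 individuals).
#' @export
sim_variant_table <- function(cfg) {
  stopifnot(inherits(cfg, "variant_sim_config"))
  set.seed(cfg$seed)
  aa <- setdiff(names(AA_AVG_MASS), "M")   # avoid M1 edge cases
  n <- cfg$n_genes * cfg$variants_per_gene
  gene <- rep(sprintf("GENE%03d", seq_len(cfg$n_genes)),
              each = cfg$variants_per_gene)
  plen <- sample(cfg$protein_length_range[1]:cfg$protein_length_range[2],
                 cfg$n_genes, replace = TRUE)[match(gene, unique(gene))]
  cls <- sample(names(cfg$class_probs), n, replace = TRUE,
                prob = cfg$class_probs)
  pos <- vapply(plen, function(L) sample(2:(L - 40), 1), integer(1))
  ref <- sample(aa, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(aa, r), 1), character(1))
  hgvs <- mapply(function(cl, p, r, a) switch(cl,
      stop_gain = paste0(r, p, "*"),
      frameshift = paste0(r, p, a, "fs*", sample(2:30, 1)),
      missense = paste0(r, p, a),
      synonymous = paste0(r, p, "=")),
    cls, pos, ref, alt)

  # truncated Beta allele frequencies via inverse-CDF on (0, 0.05]
  u <- stats::runif(n, 0, stats::pbeta(0.05, cfg$beta_shape1, cfg$beta_shape2))
  q <- pmax(stats::qbeta(u, cfg$beta_shape1, cfg$beta_shape2), 1e-6)
  f <- cfg$inbreeding_f
  p_aa <- q^2 + q * (1 - q) * f
  p_het <- 2 * q * (1 - q) * (1 - f)
  gt <- t(vapply(seq_len(n), function(i)
    stats::rmultinom(1, cfg$n_individuals,
                     c(1 - p_het[i] - p_aa[i], p_het[i], p_aa[i]))[, 1],
    numeric(3)))
  records <- data.frame(gene = gene, hgvs_p = unname(hgvs),
                        source = cfg$source,
                        het = as.integer(gt[, 2]), hom = as.integer(gt[, 3]),
                        q_true = q, stringsAsFactors = FALSE)
  truth <- data.frame(gene = gene, hgvs_p = unname(hgvs), class = cls,
                      q_true = q,
                      carriers = as.integer(gt[, 2] + gt[, 3]),
                      is_civa = cls %in% c("stop_gain", "frameshift") &
                        (gt[, 2] + gt[, 3]) >= 2,
                      stringsAsFactors = FALSE)
  list(records = records, truth = truth, config = cfg)
}

#' Simulate frame-quantized mitotic timing data
#'
#' Draws NEBD-to-anaphase-onset durations from a parametric distribution,
#' rounds them up to the acquisition frame grid and censors cells that do
#' not complete within the imaging window (such cells stay in the table as
#' non-completers, mirroring a 10-h acquisition).
#'
#' @param n_cells number of cells.
#' @param median_min target median duration in min.
#' @param distribution \code{"exponential"} (rate log(2)/median),
#'   \code{"lognormal"} (meanlog log(median), sdlog 0.5) or \code{"fixed"}.
#' @param frame_interval_min,window_min acquisition grid and window.
#' @param condition,replicate_id labels stamped on the records.
#' @param seed RNG seed.
#' @return list with \code{events} (per cell: \code{cell_id, condition,
#'   replicate_id, t_NEBD, t_AO, duration_min, completed}) and
#'   \code{truth} (the generating median and distribution).
#' @export
sim_timing <- function(n_cells = 200, median_min = 60,
                       distribution = c("exponential", "lognormal", "fixed"),
                       frame_interval_min = 6, window_min = 600,
                       condition = "WT", replicate_id = 1L, seed = 1) {
  distribution <- match.arg(distribution)
  set.seed(seed)
  d <- switch(distribution,
    exponential = stats::rexp(n_cells, rate = log(2) / median_min),
    lognormal = stats::rlnorm(n_cells, meanlog = log(median_min),
                              sdlog = 0.5),
    fixed = rep(median_min, n_cells))
  dq <- ceiling(d / frame_interval_min) * frame_interval_min
  completed <- dq <= window_min
  events <- data.frame(
    cell_id = seq_len(n_cells), condition = condition,
    replicate_id = replicate_id, t_NEBD = 0,
    t_AO = ifelse(completed, dq, NA_real_),
    duration_min = ifelse(completed, dq, NA_real_),
    completed = completed, stringsAsFactors = FALSE)
  list(events = events,
       truth = list(median_min = median_min, distribution = distribution,
                    frame_interval_min = frame_interval_min,
                    window_min = window_min))
}

#' Deterministic synthetic SPAG5-like coding sequence
#'
#' Builds a synthetic stand-in for the Astrin (SPAG5) coding sequence:
#' 1193 codons, initiator ATG, and exactly two downstream in-frame ATGs in
#' strong Kozak context placed at nt 454 (codon 152) and nt 823 (codon
#' 275) — the alternative-start geometry of the short Astrin isoforms.
#' The backbone avoids any other ATG trinucleotide, so the two planted
#' sites are the only downstream starts. This is a synthetic construction,
#' not the RefSeq sequence.
#'
#' @return a single uppercase A/C/G/T string of length 3579.
#' @export
synthetic_spag5_cds <- function() {
  n_codon <- 1193
  backbone <- rep(c("GAA", "CTT", "CCA", "GCC", "TCA", "CAG"),
                  length.out = n_codon)
  backbone[1] <- "ATG"
  # plant strong-context starts, gccaccATGG: the -6..-1 context occupies the
  # two codons before the ATG (GCC + ACC) and the +4 G is the first base of
  # the codon after it
  # codon 152 -> nt 454 (context nt 448..453, +4 at nt 457)
  backbone[150] <- "GCC"; backbone[151] <- "ACC"
  backbone[152] <- "ATG"; backbone[153] <- "GAA"
  # codon 275 -> nt 823; context nt 817..822 = codons 273-274
  backbone[273] <- "GCC"; backbone[274] <- "ACC"
  backbone[275] <- "ATG"; backbone[276] <- "GAA"
  cds <- paste(backbone, collapse = "")
  # backbone codons avoid ATG, but check junctions defensively
  hits <- gregexpr("ATG", cds, fixed = TRUE)[[1]]
  stopifnot(identical(as.integer(hits), c(1L, 454L, 823L)))
  cds
}
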