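## Seeded synthetic-data generators. Every generator is a pure function of
## its spec plus seed (RNG state is saved and restored around each call).
##
## The event clouds emulate the FSC-SSC signature of the real samples: a
## low-lying instrument-noise cloud, a central disk-shaped singlet cluster,
## and a smaller aggregate cluster at the top right whose events are treated
## as doublets -- their fluorescence is the SUM of two independent singlet
## draws, which makes the doublet-corrected mean an unbiased estimator of
## the singlet mean by construction.

.synthetic_config <- function() {
  jsonlite::read_json(system.file("extdata", "synthetic_config.json",
                                  package = "magwire"),
                      simplifyVector = TRUE)
}

#' Default G1/G2 gate pair for synthetic data
#'
#' Published with the fixed synthetic cluster geometry so gate membership in
#' tests is stable: G1 encloses the singlet and doublet clusters (excluding
#' the noise cloud), G2 the doublet cluster alone.
#'
#' @return named list of [gate()]s `G1`, `G2`.
#' @export
default_gates <- function() {
  cfg <- .synthetic_config()
  list(G1 = gate("G1", cfg$gates$G1), G2 = gate("G2", cfg$gates$G2))
}

#' Event-cloud specification
#'
#' @param n_noise,n_singlet,n_doublet cluster event counts.
#' @param singlet_fl4_mean,singlet_fl4_sd singlet fluorescence distribution
#'   (truncated normal at 0), ERF.
#' @param centers,spreads named lists (`noise`, `singlet`, `doublet`) of
#'   FSC-SSC centers and standard deviations; defaults from the published
#'   fixture config.
#' @param family FL4 noise family: `"truncated-normal"` or `"lognormal"`.
#' @param seed integer RNG seed.
#' @return object of class `event_cloud_spec`.
#' @export
event_cloud_spec <- function(n_noise = NULL, n_singlet = NULL,
                             n_doublet = NULL, singlet_fl4_mean = NULL,
                             singlet_fl4_sd = NULL, centers = NULL,
                             spreads = NULL,
                             family = c("truncated-normal", "lognormal"),
                             seed = 1L) {
  cfg <- .synthetic_config()
  if (is.null(n_noise)) n_noise <- cfg$counts$n_noise
  if (is.null(n_singlet)) n_singlet <- cfg$counts$n_singlet
  if (is.null(n_doublet)) n_doublet <- cfg$counts$n_doublet
  if (is.null(singlet_fl4_mean)) singlet_fl4_mean <- cfg$fl4$singlet_mean
  if (is.null(singlet_fl4_sd)) singlet_fl4_sd <- cfg$fl4$singlet_sd
  if (is.null(centers))
    centers <- lapply(cfg$clusters, `[[`, "center")
  if (is.null(spreads))
    spreads <- lapply(cfg$clusters, `[[`, "spread")
  if (any(c(n_noise, n_singlet, n_doublet) < 0)) .stopf("counts must be >= 0")
  if (singlet_fl4_sd <= 0) .stopf("spreads must be > 0")
  structure(list(n_noise = n_noise, n_singlet = n_singlet,
                 n_doublet = n_doublet,
                 singlet_fl4_mean = singlet_fl4_mean,
                 singlet_fl4_sd = singlet_fl4_sd,
                 centers = centers, spreads = spreads,
                 noise_fl4_mean = cfg$fl4$noise_mean,
                 noise_fl4_sd = cfg$fl4$noise_sd,
                 family = match.arg(family), seed = as.integer(seed)),
            class = "event_cloud_spec")
}

## truncated-at-zero normal via inverse CDF (exact truncation)
.rtrunc0norm <- function(n, mean, sd) {
  if (n == 0L) return(numeric(0))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

.rfl4 <- function(n, mean, sd, family) {
  if (family == "lognormal") {
    s2 <- log(1 + (sd / mean)^2)
    stats::rlnorm(n, log(mean) - s2 / 2, sqrt(s2))
  } else .rtrunc0norm(n, mean, sd)
}

#' Generate a synthetic cytometry event cloud
#'
#' Draws the three clusters of the spec; doublet FL4 values are sums of two
#' independent singlet draws. Deterministic under a fixed seed.
#'
#' @param spec an [event_cloud_spec()].
#' @param sample_id label stored on the table.
#' @return an [event_table()].
#' @export
gen_event_cloud <- function(spec, sample_id = NA_character_) {
  withr::with_seed(spec$seed, {
    blob <- function(n, cl)
      cbind(stats::rnorm(n, spec$centers[[cl]][1], spec$spreads[[cl]][1]),
            stats::rnorm(n, spec$centers[[cl]][2], spec$spreads[[cl]][2]))
    no <- blob(spec$n_noise, "noise")
    si <- blob(spec$n_singlet, "singlet")
    db <- blob(spec$n_doublet, "doublet")
    fl_no <- .rfl4(spec$n_noise, spec$noise_fl4_mean, spec$noise_fl4_sd,
                   spec$family)
    fl_si <- .rfl4(spec$n_singlet, spec$singlet_fl4_mean,
                   spec$singlet_fl4_sd, spec$family)
    fl_db <- .rfl4(spec$n_doublet, spec$singlet_fl4_mean,
                   spec$singlet_fl4_sd, spec$family) +
             .rfl4(spec$n_doublet, spec$singlet_fl4_mean,
                   spec$singlet_fl4_sd, spec$family)
    xy <- rbind(no, si, db)
    event_table(FSC = pmax(xy[, 1], 0), SSC = pmax(xy[, 2], 0),
                FL4 = c(fl_no, fl_si, fl_db), sample_id = sample_id)
  })
}

#' Calibration-experiment specification
#'
#' Describes a full synthetic run: true model parameters, one cloud per
#' channel with singlet fluorescence mean
#' `stock_mean + A (1 - exp(-B C_chan))`, where the in-channel concentration
#' `C_chan` is the spiked concentration for recombinant channels and
#' `C D / k` for neat samples, plus stock-bead reference replicates.
#'
#' @param true_A,true_B ground-truth model parameters (ERF, mL/ng).
#' @param channels data frame with columns `channel`, `role` (one of
#'   `negative`, `recombinant`, `sample`), `concentration` (ng/mL; neat for
#'   samples, in-channel for recombinant spikes).
#' @param dilution,mass_ratio sample dilution D and mass ratio k.
#' @param stock_mean,stock_sd stock-bead background fluorescence, ERF: mean
#'   per event and between-replicate jitter of the mean.
#' @param n_stock_replicates stock reference measurements per run.
#' @param cloud prototype [event_cloud_spec()] for per-channel clouds.
#' @param seed integer RNG seed.
#' @return object of class `experiment_spec`.
#' @export
experiment_spec <- function(true_A = 355.7, true_B = 0.069,
                            channels = data.frame(
                              channel = 1:5,
                              role = c("negative", "recombinant",
                                       "recombinant", "recombinant",
                                       "sample"),
                              concentration = c(0, 40, 60, 75, 250)),
                            dilution = 0.1, mass_ratio = 1.6,
                            stock_mean = 100, stock_sd = 1,
                            n_stock_replicates = 3,
                            cloud = event_cloud_spec(), seed = 1L) {
  if (true_A <= 0 || true_B <= 0) .stopf("true_A and true_B must be > 0")
  if (any(channels$concentration < 0)) .stopf("concentrations must be >= 0")
  if (!all(channels$role %in% c("negative", "recombinant", "sample")))
    .stopf("roles must be negative/recombinant/sample")
  structure(list(true_A = true_A, true_B = true_B, channels = channels,
                 dilution = dilution, mass_ratio = mass_ratio,
                 stock_mean = stock_mean, stock_sd = stock_sd,
                 n_stock_replicates = n_stock_replicates, cloud = cloud,
                 seed = as.integer(seed)),
            class = "experiment_spec")
}

#' Generate a full synthetic calibration/quantification run
#'
#' @param spec an [experiment_spec()].
#' @return list with `channels` (named list of [event_table()]s),
#'   `stock` (list of stock-bead reference tables), and `truth` (the spec's
#'   ground-truth record, including each channel's in-channel concentration
#'   and noiseless fluorescence).
#' @export
gen_calibration_experiment <- function(spec) {
  ch <- spec$channels
  C_chan <- ifelse(ch$role == "sample",
                   ch$concentration * spec$dilution / spec$mass_ratio,
                   ch$concentration)
  I_true <- saturation_model(spec$true_A, spec$true_B, C_chan)
  tables <- vector("list", nrow(ch))
  names(tables) <- paste0("channel", ch$channel)
  for (i in seq_len(nrow(ch))) {
    cl <- spec$cloud
    cl$singlet_fl4_mean <- spec$stock_mean + I_true[i]
    cl$seed <- spec$seed + 1000L * i
    tables[[i]] <- gen_event_cloud(cl, sample_id = names(tables)[i])
  }
  stock <- vector("list", spec$n_stock_replicates)
  means <- withr::with_seed(spec$seed + 77L,
    stats::rnorm(spec$n_stock_replicates, spec$stock_mean, spec$stock_sd))
  for (j in seq_len(spec$n_stock_replicates)) {
    cl <- spec$cloud
    cl$singlet_fl4_mean <- max(means[j], 0.1)
    cl$seed <- spec$seed + 500L * j + 7L
    stock[[j]] <- gen_event_cloud(cl, sample_id = paste0("stock", j))
  }
  list(channels = tables, stock = stock,
       truth = list(A = spec$true_A, B = spec$true_B,
                    channels = cbind(ch, C_channel = C_chan,
                                     I_noiseless = I_true),
                    stock_mean = spec$stock_mean,
                    dilution = spec$dilution, mass_ratio = spec$mass_ratio))
}

#' Seeded uniform bead positions in the channel
#'
#' Rejection-samples positions uniformly over the duct cross-section
#' excluding the wire envelope, uniform along the channel length.
#'
#' @param n number of beads.
#' @param channel a [channel_geometry()].
#' @param seed integer RNG seed.
#' @param bead_radius bead radius added to the wire envelope, um.
#' @return n x 3 matrix, um: columns `x` (width), `z` (height), `y` (axial).
#' @export
gen_bead_positions <- function(n, channel = channel_geometry(), seed = 1L,
                               bead_radius = 1.5) {
  if (n < 0) .stopf("n must be >= 0")
  r_excl <- channel$wire$glass_outer_radius + bead_radius
  withr::with_seed(as.integer(seed), {
    xs <- zs <- numeric(0)
    while (length(xs) < n) {
      m <- max(2 * (n - length(xs)), 16)
      x <- stats::runif(m, -channel$width / 2, channel$width / 2)
      z <- stats::runif(m, -channel$height / 2, channel$height / 2)
      ok <- x^2 + z^2 > r_excl^2
      xs <- c(xs, x[ok]); zs <- c(zs, z[ok])
    }
    y <- stats::runif(n, 0, channel$length * 1e4)
    cbind(x = xs[seq_len(n)], z = zs[seq_len(n)], y = y)
  })
}
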