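# Seeded generator of PBMC-like FCS datasets with ground-truth labels.
#
# Events are drawn from a Gaussian mixture on a log10 latent scale (units:
# decades of a 10^5-count digitizer range), exponentiated to channel
# counts, mixed by a spillover matrix on the eight fluorescence channels,
# and clipped to [0, $PnR).  The default populations encode qualitative
# marker logic only (monocytes CD14-high, pDC CD123-high, mDC CD11c-high,
# B cells MHC-II-high, debris low-scatter); cytokine channels are bimodal
# within the antigen-presenting populations to emulate a stimulation
# response.  Real LSR II distributions are not claimed.

#' Specify one mixture population
#'
#' @param name population name.
#' @param weight mixture proportion.
#' @param mean length-10 latent mean (log10 channel units, one entry per
#'   channel in [SYNTH_CHANNELS] order).
#' @param covariance 10 x 10 positive-definite latent covariance.
#' @param responder_fraction fraction of events that respond to
#'   stimulation by up-regulating cytokines (0 for non-APC populations).
#' @param responder_shift length-4 latent shift added to the cytokine
#'   channels of responders.
#' @return list of class `population_spec`.
#' @export
population_spec <- function(name, weight, mean, covariance,
                            responder_fraction = 0,
                            responder_shift = numeric(4)) {
  mean <- as.numeric(mean)
  covariance <- as.matrix(covariance)
  stopifnot(length(mean) == 10L, all(dim(covariance) == 10L))
  ok <- tryCatch(
    {
      chol(covariance)
      TRUE
    },
    error = function(e) FALSE
  )
  if (!ok) {
    cyto_error("synth_config_error", sprintf(
      "population '%s': covariance is not positive definite", name
    ))
  }
  structure(
    list(
      name = name, weight = weight, mean = mean, covariance = covariance,
      responder_fraction = responder_fraction,
      responder_shift = as.numeric(responder_shift)
    ),
    class = "population_spec"
  )
}

#' Default PBMC-like population specifications
#'
#' Read from the checked-in tuning file
#' `system.file("extdata/pbmc_populations.csv", package = "cytostd")`:
#' seven populations (monocytes, mDC, pDC, B cells, debris/dead and two
#' novel populations) with diagonal latent covariances.
#'
#' @return named list of [population_spec()] objects.
#' @export
default_populations <- function() {
  path <- system.file("extdata", "pbmc_populations.csv", package = "cytostd")
  df <- utils::read.csv(path, check.names = FALSE)
  specs <- lapply(seq_len(nrow(df)), function(i) {
    population_spec(
      name = df$name[i],
      weight = df$weight[i],
      mean = as.numeric(df[i, SYNTH_CHANNELS]),
      covariance = diag(rep(df$sd[i]^2, 10)),
      responder_fraction = df$responder_fraction[i],
      responder_shift = as.numeric(df[i, paste0("shift_", SYNTH_CYTOKINE_CHANNELS)])
    )
  })
  stats::setNames(specs, df$name)
}

#' Default spillover matrix for the eight fluorescence channels
#'
#' Crosstalk decays geometrically with detector distance
#' (`0.12 * 0.5^(|i-j|-1)` off the diagonal), a magnitude typical of
#' neighbouring emission filters.
#'
#' @return a [spillover_matrix()].
#' @export
default_spillover <- function() {
  k <- length(SYNTH_FLUOR_CHANNELS)
  S <- outer(seq_len(k), seq_len(k), function(i, j) {
    ifelse(i == j, 1, 0.12 * 0.5^(abs(i - j) - 1))
  })
  spillover_matrix(S, SYNTH_FLUOR_CHANNELS)
}

#' Generator configuration
#'
#' @param n_events events per sample (>= 1).
#' @param seed integer seed fixing all randomness.
#' @param populations named list of [population_spec()]s whose weights sum
#'   to 1.
#' @param spillover [spillover_matrix()] over the fluorescence channels.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_events = 12000, seed = 1,
                         populations = default_populations(),
                         spillover = default_spillover()) {
  if (n_events < 1) cyto_error("synth_config_error", "n_events must be >= 1")
  w <- vapply(populations, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-9) {
    cyto_error("synth_config_error", sprintf(
      "population weights sum to %.6f, not 1", sum(w)
    ))
  }
  structure(
    list(
      n_events = as.integer(n_events), seed = as.integer(seed),
      populations = populations, spillover = spillover,
      channels = SYNTH_CHANNELS
    ),
    class = "synth_config"
  )
}

#' Simulate one PBMC-like sample
#'
#' @param config a [synth_config()].
#' @return list with `dataset` (an [fcs_dataset()] carrying the spillover
#'   in `$SPILLOVER`), `labels` (factor of true population names, one per
#'   event) and `true_events` (the event matrix before spillover was
#'   applied, for ground-truth checks).  The same config always yields the
#'   same result.
#' @export
simulate_sample <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_events
  pops <- config$populations
  w <- vapply(pops, `[[`, numeric(1), "weight")
  labels <- sample(names(pops), n, replace = TRUE, prob = w)
  cyt_idx <- match(SYNTH_CYTOKINE_CHANNELS, SYNTH_CHANNELS)

  latent <- matrix(0, n, 10)
  for (pn in names(pops)) {
    rows <- which(labels == pn)
    if (!length(rows)) next
    p <- pops[[pn]]
    latent[rows, ] <- MASS::mvrnorm(length(rows), mu = p$mean, Sigma = p$covariance)
    if (p$responder_fraction > 0) {
      resp <- stats::rbinom(length(rows), 1, p$responder_fraction) == 1
      if (any(resp)) {
        latent[rows[resp], cyt_idx] <- latent[rows[resp], cyt_idx] +
          matrix(p$responder_shift, sum(resp), 4, byrow = TRUE)
      }
    }
  }
  true_events <- 10^latent
  colnames(true_events) <- config$channels

  events <- apply_spillover(true_events, config$spillover)
  events[events < 0] <- 0
  clip <- SYNTH_RANGE * (1 - 1e-6)
  events[events > clip] <- clip

  dataset <- fcs_dataset(
    events,
    channels = config$channels,
    ranges = SYNTH_RANGE,
    displays = c(
      rep("Linear,0,100000", 2),
      rep("Logarithmic,5,1", 8)
    ),
    keywords = c(
      "$SPILLOVER" = serialize_spillover_keyword(config$spillover),
      "$ORIGINALITY" = "Original",
      "$CYT" = "cytostd synthetic generator"
    )
  )
  list(
    dataset = dataset,
    labels = factor(labels, levels = names(pops)),
    true_events = true_events
  )
}
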