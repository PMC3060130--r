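# End-to-end analytical pipeline on synthetic data: preprocessing,
# manual-style gating, mixture-model clustering, cluster matching,
# comparison, and assembly of a complete example ACS container.

#' Preprocess a dataset: live gate, compensate, subset channels
#'
#' @param dataset an [fcs_dataset()].
#' @param strategy a [gating_strategy()] containing the live-cell gate.
#' @param spill optional [spillover_matrix()]; defaults to the dataset's
#'   own `$SPILLOVER` keyword.
#' @param keep_channels channels retained in the output (default: all).
#' @param live_gate id of the gate selecting live cells (default: the
#'   first parentless gate in the strategy).
#' @return a valid [fcs_dataset()] with dead cells/debris removed, events
#'   compensated, and columns subset; `$TOT`/`$PAR` are rederived on
#'   write.  An empty selection yields an empty dataset with a warning,
#'   not an error.
#' @export
preprocess <- function(dataset, strategy, spill = NULL, keep_channels = NULL,
                       live_gate = NULL) {
  if (is.null(live_gate)) {
    roots <- names(strategy$gates)[vapply(strategy$gates, function(g) is.null(g$parent_id), TRUE)]
    if (!length(roots)) cyto_error("gate_error", "strategy has no parentless live-cell gate")
    live_gate <- roots[1]
  }
  live <- evaluate_gate(strategy, live_gate, dataset)
  if (!any(live)) cyto_warn("live gate selected 0 events; returning an empty dataset")
  out <- subset_events(dataset, rows = live)
  out <- compensate_dataset(out, spill)
  if (!is.null(keep_channels)) out <- subset_events(out, channels = keep_channels)
  out
}

#' Cluster events with a Gaussian mixture model
#'
#' Events are moved to an inverse-hyperbolic-sine scale
#' (`asinh(x / cofactor)`), where log-normally distributed channel
#' intensities are approximately Gaussian, and fitted with a
#' full-covariance Gaussian mixture (EM, model-based hierarchical
#' initialization on a seeded subsample).  Posterior responsibilities are
#' returned as a fuzzy CLR table whose rows sum to 1.
#'
#' @param dataset an [fcs_dataset()].
#' @param k number of mixture components (>= 1).
#' @param seed integer; fixes the initialization subsample, making the fit
#'   deterministic.
#' @param channels channels to cluster on (default: all).
#' @param cofactor asinh cofactor in channel units (default 150, a common
#'   choice for conventional flow intensities).
#' @param restarts maximum number of re-initializations when EM degenerates.
#' @return a [clr_table()] with classes `cluster1..clusterk`.
#' @export
auto_cluster <- function(dataset, k, seed = 1, channels = NULL,
                         cofactor = 150, restarts = 5) {
  n <- n_events(dataset)
  if (k < 1) cyto_error("cluster_error", "k must be >= 1")
  if (n < k) cyto_error("cluster_error", sprintf("need n_events >= k (%d < %d)", n, k))
  X <- dataset$events
  if (!is.null(channels)) X <- X[, channel_index(dataset, channels), drop = FALSE]
  X <- asinh(X / cofactor)
  if (k == 1L) {
    return(clr_table(matrix(1, n, 1), "cluster1"))
  }
  fit <- NULL
  for (r in seq_len(restarts)) {
    set.seed(seed + (r - 1L) * 1000L)
    sub <- sample.int(n, min(n, 1500L))
    fit <- tryCatch(
      suppressWarnings(mclust::Mclust(X,
        G = k, modelNames = "VVV", verbose = FALSE,
        initialization = list(subset = sub)
      )),
      error = function(e) NULL
    )
    if (!is.null(fit) && !is.null(fit$z)) break
    fit <- NULL
  }
  if (is.null(fit)) {
    cyto_error("cluster_error", sprintf(
      "EM failed to produce %d non-degenerate components after %d restarts", k, restarts
    ))
  }
  z <- fit$z
  z <- z / rowSums(z)
  clr_table(z, paste0("cluster", seq_len(k)))
}

#' Match clusters to reference populations
#'
#' Builds the contingency table between hard assignments of the two
#' tables and maps each cluster to the reference class that maximizes
#' total overlap (Hungarian assignment).  Clusters left without a
#' reference class (or with zero overlap) are labeled `"novel"`.
#'
#' @param clr [clr_table()] of cluster responsibilities.
#' @param reference [clr_table()] of reference (e.g. manually gated)
#'   populations, same event count.
#' @return named character vector: cluster label -> reference label or
#'   `"novel"`.
#' @export
match_clusters <- function(clr, reference) {
  stopifnot(
    inherits(clr, "clr_table"), inherits(reference, "clr_table"),
    nrow(clr$memberships) == nrow(reference$memberships)
  )
  a <- hard_assignment(clr, threshold = 0)
  b <- hard_assignment(reference, threshold = 0)
  tab <- table(
    factor(a, levels = clr$class_labels),
    factor(b, levels = reference$class_labels)
  )
  sol <- solve_assignment_max(unclass(tab))
  out <- rep("novel", length(clr$class_labels))
  for (i in seq_along(sol)) {
    if (sol[i] > 0L && tab[i, sol[i]] > 0) {
      out[i] <- reference$class_labels[sol[i]]
    }
  }
  stats::setNames(out, clr$class_labels)
}

#' Compare automated and manual classifications
#'
#' @param manual reference [clr_table()] (e.g. from gate memberships).
#' @param automated [clr_table()] of cluster responsibilities.
#' @param mapping cluster -> population mapping from [match_clusters()];
#'   computed when `NULL`.
#' @param threshold hard-assignment threshold (default 0.5; events under
#'   it count as unclassified).
#' @return object of class `comparison_result`: `per_population` data
#'   frame with precision, recall and F-measure (`F = 2PR/(P+R)`, 0 when
#'   `P + R = 0`), `contingency` table (manual x automated clusters), and
#'   `mean_f`.
#' @export
compare_classifications <- function(manual, automated, mapping = NULL,
                                    threshold = 0.5) {
  stopifnot(nrow(manual$memberships) == nrow(automated$memberships))
  if (is.null(mapping)) mapping <- match_clusters(automated, manual)
  m <- hard_assignment(manual, threshold = threshold)
  a_raw <- hard_assignment(automated, threshold = threshold)
  a <- ifelse(a_raw == "unclassified", "unclassified", unname(mapping[a_raw]))
  per <- do.call(rbind, lapply(manual$class_labels, function(cl) {
    tp <- sum(m == cl & a == cl)
    fp <- sum(m != cl & a == cl)
    fn <- sum(m == cl & a != cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    data.frame(
      population = cl, tp = tp, fp = fp, fn = fn,
      precision = p, recall = r, f_measure = f,
      stringsAsFactors = FALSE
    )
  }))
  structure(
    list(
      per_population = per,
      contingency = table(manual = m, automated = a_raw),
      mapping = mapping,
      mean_f = mean(per$f_measure)
    ),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result>\n")
  print(x$per_population[, c("population", "precision", "recall", "f_measure")],
    row.names = FALSE
  )
  cat(sprintf("  mean F-measure: %.4f\n", x$mean_f))
  invisible(x)
}

# Channels retained after preprocessing: scatter + surface markers.
EXAMPLE_KEEP_CHANNELS <- SYNTH_CHANNELS[1:6]
EXAMPLE_POPULATIONS <- c("monocytes", "mDC", "pDC", "B cells")

#' The manual-style gating strategy used by the example pipeline
#'
#' A scatter rectangle selects live cells (debris and dead cells are
#' low-scatter); four child gates pick the populations on marker pairs in
#' log display space: monocytes (CD14-high, ellipsoid on CD14/CD11c), pDC
#' (CD123-high, ellipsoid on CD123/CD11c), mDC (CD11c-high CD14-low,
#' polygon on CD11c/CD14) and B cells (MHC-II-high CD11c-low, polygon on
#' MHC-II/CD11c).
#'
#' @return a [gating_strategy()].
#' @export
example_gating_strategy <- function() {
  lg <- transform_scale("flog", T = SYNTH_RANGE, M = 5, id = "log5")
  dim_log <- function(ch) gate_dimension(ch, transform_ref = "log5")
  box <- function(cx, cy, half) {
    cbind(
      c(cx - half, cx + half, cx + half, cx - half),
      c(cy - half, cy - half, cy + half, cy + half)
    ) / 5
  }
  sd_disp <- 0.1 / 5 # one latent decade-sd in display units
  gates <- list(
    rectangle_gate("live",
      dims = list(gate_dimension("FSC-A"), gate_dimension("SSC-A")),
      mins = c(8900, 1000), maxs = c(Inf, Inf)
    ),
    ellipsoid_gate("monocytes",
      dims = list(dim_log("CD14"), dim_log("CD11c")),
      mean = c(4.1, 3.2) / 5, covariance = diag(sd_disp^2, 2),
      distance_square = 20, parent_id = "live"
    ),
    ellipsoid_gate("pDC",
      dims = list(dim_log("CD123"), dim_log("CD11c")),
      mean = c(4.05, 1.5) / 5, covariance = diag(sd_disp^2, 2),
      distance_square = 20, parent_id = "live"
    ),
    polygon_gate("mDC",
      dims = list(dim_log("CD11c"), dim_log("CD14")),
      vertices = box(4.1, 1.9, 0.45), parent_id = "live"
    ),
    polygon_gate("B cells",
      dims = list(dim_log("MHC-II"), dim_log("CD11c")),
      vertices = box(4.5, 1.4, 0.45), parent_id = "live"
    )
  )
  gating_strategy(gates, transforms = list(lg))
}

#' Build the example ACS container
#'
#' Reproduces the reference analytical workflow end to end on synthetic
#' data: two PBMC-like samples are simulated, preprocessed (live gate,
#' compensation, channel subsetting), gated manually-style, clustered
#' with a Gaussian mixture, and bundled as an ACS container holding 2 raw
#' FCS files, 2 preprocessed FCS files, 2 gate-description XML files, 2
#' CLR files and the XML table of contents, with relations encoding the
#' workflow.  Identical seeds yield byte-identical containers.
#'
#' @param seed integer master seed.
#' @param path optional output path for the `.acs` file.
#' @param n_events events per simulated sample.
#' @param k mixture components for the clustering stage (default 6: the
#'   live populations, including the two novel ones).
#' @return list of class `example_build` with `container`, `bytes`,
#'   `comparisons` (one [compare_classifications()] result per sample)
#'   and `mean_f`.
#' @export
build_example_acs <- function(seed = 42, path = NULL, n_events = 12000, k = 6) {
  strategy <- example_gating_strategy()
  gml_text <- write_gatingml(strategy)
  members <- list()
  entries <- list()
  relations <- list()
  comparisons <- list()

  for (i in 1:2) {
    sim <- simulate_sample(synth_config(n_events = n_events, seed = seed + i - 1L))
    raw_uri <- sprintf("fcs/sample%d.fcs", i)
    pre_uri <- sprintf("fcs/sample%d_preprocessed.fcs", i)
    gml_uri <- sprintf("gating/sample%d_gates.xml", i)
    clr_uri <- sprintf("clr/sample%d_clusters.csv", i)

    pre <- preprocess(sim$dataset, strategy,
      keep_channels = EXAMPLE_KEEP_CHANNELS, live_gate = "live"
    )
    manual <- evaluate_all(strategy, pre)
    manual_clr <- clr_from_memberships(
      manual$membership[EXAMPLE_POPULATIONS],
      EXAMPLE_POPULATIONS
    )
    auto <- auto_cluster(pre, k = k, seed = seed + 100L + i)
    auto$source_ref <- basename(pre_uri)
    comparisons[[i]] <- compare_classifications(manual_clr, auto)

    members[[raw_uri]] <- write_fcs(sim$dataset)
    members[[pre_uri]] <- write_fcs(pre)
    members[[gml_uri]] <- charToRaw(gml_text)
    members[[clr_uri]] <- charToRaw(write_clr(auto))
    entries <- c(entries, list(
      acs_entry(raw_uri, "application/vnd.isac.fcs", role = "raw data"),
      acs_entry(pre_uri, "application/vnd.isac.fcs", role = "preprocessed data"),
      acs_entry(gml_uri, "application/xml+gating-ml", role = "manual gating description"),
      acs_entry(clr_uri, "text/csv+clr", role = "automated classification results")
    ))
    relations <- c(relations, list(
      acs_relation(pre_uri, raw_uri, "preprocessed-from"),
      acs_relation(gml_uri, pre_uri, "gating-description-of"),
      acs_relation(clr_uri, pre_uri, "classification-results-of")
    ))
  }

  container <- acs_container(members, entries, relations)
  bytes <- acs_pack(container, path = path)
  structure(
    list(
      container = container, bytes = bytes,
      comparisons = comparisons,
      mean_f = mean(vapply(comparisons, `[[`, numeric(1), "mean_f"))
    ),
    class = "example_build"
  )
}

#' Verify an example container by replaying it
#'
#' Re-opens a container produced by [build_example_acs()], validates its
#' integrity, and replays the shipped gate descriptions against the
#' shipped FCS files: the live gate applied to each raw file must select
#' exactly the events of the matching preprocessed file, and each CLR
#' file must classify exactly those events.
#'
#' @param bytes_or_path `.acs` bytes or file path.
#' @return list with `ok`, `findings` (from [acs_validate()]) and `checks`
#'   (data frame of replay checks).
#' @export
verify_example_acs <- function(bytes_or_path) {
  container <- acs_unpack(bytes_or_path)
  findings <- acs_validate(container)
  checks <- list()
  g <- acs_relation_graph(container)
  pre_edges <- g$edges[g$edges$relationship == "preprocessed-from", , drop = FALSE]
  for (ri in seq_len(nrow(pre_edges))) {
    pre_uri <- pre_edges$subject[ri]
    raw_uri <- pre_edges$object[ri]
    raw_ds <- read_fcs(container$members[[raw_uri]])
    pre_ds <- read_fcs(container$members[[pre_uri]])
    gml_uri <- g$edges$subject[g$edges$relationship == "gating-description-of" &
      g$edges$object == pre_uri][1]
    strategy <- read_gatingml(rawToChar(container$members[[gml_uri]]))
    roots <- names(strategy$gates)[vapply(strategy$gates, function(x) is.null(x$parent_id), TRUE)]
    live_n <- sum(evaluate_gate(strategy, roots[1], raw_ds))
    checks[[length(checks) + 1L]] <- data.frame(
      check = sprintf("live gate on %s reproduces %s event count", raw_uri, pre_uri),
      ok = live_n == n_events(pre_ds), stringsAsFactors = FALSE
    )
    clr_uri <- g$edges$subject[g$edges$relationship == "classification-results-of" &
      g$edges$object == pre_uri][1]
    clr <- read_clr(rawToChar(container$members[[clr_uri]]))
    checks[[length(checks) + 1L]] <- data.frame(
      check = sprintf("%s rows match %s event count", clr_uri, pre_uri),
      ok = nrow(clr$memberships) == n_events(pre_ds), stringsAsFactors = FALSE
    )
  }
  checks <- do.call(rbind, checks)
  list(
    ok = !nrow(findings[findings$level == "error", , drop = FALSE]) && all(checks$ok),
    findings = findings,
    checks = checks
  )
}
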