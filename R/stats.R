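#' Spearman rank correlation with average ranks for ties
#'
#' Pearson correlation of the average-ranked vectors. Returns `NA` (an
#' undefined-result signal, not an error) when either input is constant.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return rho in `[-1, 1]`, or `NA` if undefined.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

#' Correlate descriptors with response probabilities
#'
#' One Spearman coefficient per (descriptor, response) pair with
#' pairwise deletion of missing values; `n` reports the complete pairs
#' used. Fewer than 3 complete pairs, or a constant column, yields `NA`.
#'
#' @param table Descriptor table (one row per species) with response
#'   columns joined.
#' @param descriptors Descriptor column names; defaults to every numeric
#'   descriptor the table carries.
#' @param responses Response column names present in `table`.
#' @return `data.frame` with columns `descriptor`, `response`, `rho`,
#'   `n`.
#' @export
correlate_features <- function(table,
                               descriptors = NULL,
                               responses = c("cluster_probability",
                                             "bridging_probability")) {
  if (is.null(descriptors)) {
    cand <- c("mass", "formal_charge", "dbe", "aromatic_ring_count",
              "carboxylic_acid_count", "n_amine_count", "o_to_c", "h_to_c",
              "polar_sasa", "apolar_sasa", "total_sasa", "logp")
    descriptors <- intersect(cand, names(table))
  }
  responses <- intersect(responses, names(table))
  if (!length(responses)) stop("no response columns found in table")
  out <- expand.grid(descriptor = descriptors, response = responses,
                     stringsAsFactors = FALSE)
  out$rho <- NA_real_
  out$n <- 0L
  for (r in seq_len(nrow(out))) {
    x <- table[[out$descriptor[r]]]
    y <- table[[out$response[r]]]
    ok <- is.finite(x) & is.finite(y)
    out$n[r] <- sum(ok)
    if (sum(ok) >= 3) out$rho[r] <- spearman_rho(x[ok], y[ok])
  }
  out
}

#' Ordinary least squares fit of probability vs mass below a threshold
#'
#' Fits `probability ~ mass` on the species lighter than `threshold`
#' (strictly below); points at or above the threshold never influence
#' the fit.
#'
#' @param masses,probabilities Equal-length numeric vectors.
#' @param threshold Mass cutoff in Da.
#' @return List with `slope`, `intercept`, `n`, `threshold`.
#' @export
segmented_mass_fit <- function(masses, probabilities, threshold = 200) {
  stopifnot(length(masses) == length(probabilities))
  sel <- is.finite(masses) & is.finite(probabilities) & masses < threshold
  if (sum(sel) < 2)
    stop("need at least 2 species below the threshold")
  ft <- lm(probabilities[sel] ~ masses[sel])
  cf <- coef(ft)
  list(slope = unname(cf[2]), intercept = unname(cf[1]),
       n = sum(sel), threshold = threshold)
}

#' Average per-replica summaries over a temperature ensemble
#'
#' Unweighted mean over replicas of frame-averaged quantities, with the
#' across-replica standard deviation. Replicas must share an identical
#' schema (same names, same lengths).
#'
#' @param replicas List of per-replica summaries. Each summary is a list
#'   of named numeric vectors and/or data.frames of numerics.
#' @return List of class `maom_ensemble_summary` with `mean` and `sd`
#'   mirroring the replica schema, plus `n_replicas`.
#' @export
ensemble_average <- function(replicas) {
  if (!length(replicas)) stop("at least one replica is required")
  ref <- replicas[[1]]
  nm <- names(ref)
  for (r in replicas)
    if (!identical(names(r), nm)) stop("replica schema mismatch")
  avg_one <- function(get) {
    lapply(nm, function(k) {
      vals <- lapply(replicas, `[[`, k)
      if (is.data.frame(ref[[k]])) {
        num <- vapply(ref[[k]], is.numeric, logical(1))
        for (v in vals)
          if (!identical(dim(v), dim(ref[[k]])))
            stop("replica schema mismatch in '", k, "'")
        out <- ref[[k]]
        for (cn in names(num)[num]) {
          m <- vapply(vals, function(v) v[[cn]], numeric(nrow(out)))
          m <- matrix(m, nrow = nrow(out))
          out[[cn]] <- apply(m, 1, get)
        }
        out
      } else {
        m <- vapply(vals, function(v) as.numeric(v),
                    numeric(length(ref[[k]])))
        m <- matrix(m, nrow = length(ref[[k]]))
        setNames(apply(m, 1, get), names(ref[[k]]))
      }
    }) -> res
    names(res) <- nm
    res
  }
  structure(list(mean = avg_one(mean),
                 sd = avg_one(function(x) if (length(replicas) > 1) sd(x) else 0),
                 n_replicas = length(replicas)),
            class = "maom_ensemble_summary")
}

#' Write the analysis report
#'
#' Emits CSV tables (per-species probabilities, correlations, coverage,
#' adsorbed percentages) and a JSON manifest recording the inputs,
#' configuration and seed. Output is byte-deterministic under fixed
#' inputs.
#'
#' @param summary A `maom_ensemble_summary` (or compatible list).
#' @param correlations Correlation `data.frame` from
#'   [correlate_features()].
#' @param out_dir Output directory.
#' @param manifest Named list of run metadata (seed, preset, cutoffs...).
#' @return Character vector of written file paths, invisibly.
#' @export
write_report <- function(summary, correlations, out_dir, manifest = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit_csv <- function(obj, name) {
    p <- file.path(out_dir, name)
    write.csv(obj, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  mu <- if (inherits(summary, "maom_ensemble_summary")) summary$mean else summary
  for (k in names(mu)) {
    obj <- mu[[k]]
    if (is.data.frame(obj)) emit_csv(obj, paste0(k, ".csv"))
    else emit_csv(data.frame(name = names(obj), value = as.numeric(obj)),
                  paste0(k, ".csv"))
  }
  if (inherits(summary, "maom_ensemble_summary")) {
    for (k in names(summary$sd)) {
      obj <- summary$sd[[k]]
      if (!is.data.frame(obj))
        emit_csv(data.frame(name = names(obj), value = as.numeric(obj)),
                 paste0(k, "_sd.csv"))
    }
  }
  emit_csv(correlations, "correlations.csv")
  manifest$package_version <- as.character(utils::packageVersion("maomtools"))
  manifest$r_version <- paste(R.version$major, R.version$minor, sep = ".")
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths <- c(paths, mpath)
  invisible(paths)
}
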