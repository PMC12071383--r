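# Aggregate statistics over a profile table.

# Half-away-from-zero rounding (printed percentages use this, not banker's
# rounding).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarize a profile table by cluster
#'
#' Computes, over the profiled rows: counts and percentages per cluster
#' (percentages rounded half-away-from-zero to 1 decimal), the
#' pocket-candidate count and its percentage of cluster 2, mean and
#' standard deviation of the V/v volume ratio per cluster, and the
#' amino-acid composition of each cluster (wild-type and mutant residues,
#' percent within cluster).
#'
#' @param profile A `profile_table` from [profile_variants()].
#' @return A `cluster_summary` list with elements `n_profiled`, `counts`,
#'   `percentages`, `pocket` (count, pct_of_cluster2), `v_ratio` (mean/sd
#'   per cluster), `composition` (list of two 20 x 3 matrices `wild` and
#'   `mutant`).
#' @export
summarize_clusters <- function(profile) {
  p <- profile[!is.na(profile$status) & profile$status == "profiled", ,
               drop = FALSE]
  if (!nrow(p)) stop("no profiled rows to summarize")
  total <- nrow(p)
  counts <- vapply(1:3, function(k) sum(p$cluster == k), integer(1))
  names(counts) <- paste0("cluster", 1:3)
  pct <- round_half_up(100 * counts / total, 1)
  pocket_n <- sum(p$pocket_candidate & p$cluster == 2L, na.rm = TRUE)
  pocket_pct <- if (counts[2] > 0)
    unname(round_half_up(100 * pocket_n / counts[2], 1)) else NA_real_
  vr <- lapply(1:3, function(k) {
    x <- p$v_ratio[p$cluster == k]
    c(mean = if (length(x)) mean(x) else NA_real_,
      sd = if (length(x) > 1) stats::sd(x) else NA_real_)
  })
  names(vr) <- names(counts)
  comp <- function(col) {
    m <- matrix(0, nrow = 20, ncol = 3,
                dimnames = list(standard_aa(), names(counts)))
    for (k in 1:3) {
      if (counts[k] == 0) next
      tab <- table(factor(p[[col]][p$cluster == k], levels = standard_aa()))
      m[, k] <- round_half_up(100 * as.numeric(tab) / counts[k], 1)
    }
    m
  }
  structure(list(n_profiled = total, counts = counts,
                 percentages = pct,
                 pocket = list(count = pocket_n,
                               pct_of_cluster2 = pocket_pct),
                 v_ratio = vr,
                 composition = list(wild = comp("wild_aa"),
                                    mutant = comp("mutant_aa"))),
            class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat(format_cluster_summary(x), sep = "\n")
  invisible(x)
}

#' Human-readable cluster summary
#'
#' @param x A `cluster_summary`.
#' @return Character vector of report lines (fixed formatting, no
#'   timestamps).
#' @export
format_cluster_summary <- function(x) {
  lines <- c(
    sprintf("profiled sites: %d", x$n_profiled),
    sprintf("cluster %d (%s): %d sites (%.1f%%)",
            1:3, c("inner layer", "outer layer", "intermediate"),
            x$counts, x$percentages),
    sprintf("pocket candidates (cluster 2, V/v > threshold): %d (%s%% of cluster 2)",
            x$pocket$count,
            if (is.na(x$pocket$pct_of_cluster2)) "NA"
            else sprintf("%.1f", x$pocket$pct_of_cluster2)))
  for (k in 1:3) {
    vr <- x$v_ratio[[k]]
    lines <- c(lines, sprintf(
      "cluster %d V/v: mean %s, sd %s", k,
      if (is.na(vr["mean"])) "NA" else sprintf("%.2f", vr["mean"]),
      if (is.na(vr["sd"])) "NA" else sprintf("%.2f", vr["sd"])))
  }
  lines
}

#' Write a cluster summary as JSON
#'
#' @param x A `cluster_summary`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_summary_json <- function(x, path) {
  obj <- list(
    n_profiled = x$n_profiled,
    counts = as.list(x$counts),
    percentages = as.list(x$percentages),
    pocket = x$pocket,
    v_ratio = lapply(x$v_ratio, as.list),
    composition = list(wild = as.data.frame(x$composition$wild),
                       mutant = as.data.frame(x$composition$mutant)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
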