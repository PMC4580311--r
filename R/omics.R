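# Differential-regulation calling for transcripts and proteins, and the
# transcript-protein co-regulation classification and correlation.

#' Benjamini-Yekutieli adjustment of p-values
#'
#' Step-up false-discovery-rate control valid under arbitrary dependence
#' (the c(m) = sum(1/i) corrected variant), as applied to the microarray
#' p-values. Thin, validated wrapper over `stats::p.adjust(method = "BY")`.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values (monotone in rank, capped at 1).
#' @export
by_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BY")
}

#' Transcript differential-expression call
#'
#' Up if FC >= 1.5 and adjusted p < 0.05; down if FC <= 1/1.5 and adjusted
#' p < 0.05; otherwise unchanged. The fold-change cutoff is inclusive
#' (FC = 1.5 counts as regulated).
#'
#' @param log2fc log2 fold change (condition B over A).
#' @param adj_p Benjamini-Yekutieli adjusted p-value.
#' @param fc_cutoff linear fold-change cutoff (default 1.5).
#' @param p_cutoff adjusted-p cutoff (default 0.05).
#' @return character vector in `{"up", "down", "unchanged"}` (`NA` input
#'   gives `NA`).
#' @export
call_transcript <- function(log2fc, adj_p, fc_cutoff = 1.5, p_cutoff = 0.05) {
  lc <- log2(fc_cutoff)
  out <- ifelse(is.na(log2fc) | is.na(adj_p), NA_character_,
         ifelse(log2fc >= lc & adj_p < p_cutoff, "up",
         ifelse(log2fc <= -lc & adj_p < p_cutoff, "down", "unchanged")))
  out
}

#' Protein differential-abundance call
#'
#' Two-tier significance: |FC| > 1.5 with p < 0.1, or 1.3 < |FC| <= 1.5
#' with p < 0.05 - in either case more than half of the replicates in which
#' the protein was identified must agree in direction. |FC| <= 1.3 with
#' p > 0.05 is called unchanged; records meeting neither rule are excluded
#' from further analysis. Fold-change magnitude is symmetric:
#' |FC| = max(FC, 1/FC) on the linear scale.
#'
#' @param log2fc mean log2 fold change over replicates.
#' @param p p-value of the protein ratio (t-distribution based).
#' @param consistency fraction of identified replicates sharing the sign of
#'   the mean fold change.
#' @return character vector in `{"up", "down", "unchanged", "excluded"}`.
#' @export
call_protein <- function(log2fc, p, consistency = 1) {
  n <- max(length(log2fc), length(p), length(consistency))
  log2fc <- rep_len(log2fc, n); p <- rep_len(p, n)
  consistency <- rep_len(consistency, n)
  mag <- abs(log2fc)  # |log2 FC|; FC-magnitude thresholds on log2 scale
  tier1 <- mag > log2(1.5) & p < 0.1
  tier2 <- mag > log2(1.3) & mag <= log2(1.5) & p < 0.05
  sig <- (tier1 | tier2) & consistency > 0.5
  unch <- mag <= log2(1.3) & p > 0.05
  out <- ifelse(is.na(log2fc) | is.na(p), NA_character_,
         ifelse(sig & log2fc > 0, "up",
         ifelse(sig & log2fc < 0, "down",
         ifelse(unch, "unchanged", "excluded"))))
  out
}

#' Classify transcript-protein pairs into co-regulation groups
#'
#' Places each gene into the 3x3 grid of (transcript call x protein call);
#' the unchanged/unchanged cell is the background, the remaining non-empty
#' cells are the co-regulation groups. Pairs with an `NA` call form their
#' own `NA` category and are not counted in the differential fraction's
#' denominator.
#'
#' @param pairs data.frame with columns `gene`, `transcript_call`,
#'   `protein_call`.
#' @return list: `pairs` with a `group` column, `counts` (group sizes),
#'   `n_background`, `n_differential`, `differential_fraction`.
#' @export
classify_pairs <- function(pairs) {
  tc <- pairs$transcript_call; pc <- pairs$protein_call
  grp <- ifelse(is.na(tc) | is.na(pc), "not_available",
         ifelse(tc == "unchanged" & pc == "unchanged", "background",
                paste0("transcript_", tc, "/protein_", pc)))
  pairs$group <- grp
  counts <- table(grp)
  complete <- grp != "not_available"
  n_bg <- sum(grp == "background")
  n_diff <- sum(complete) - n_bg
  list(pairs = pairs, counts = counts, n_background = n_bg,
       n_differential = n_diff,
       differential_fraction = if (sum(complete)) n_diff / sum(complete)
                               else NA_real_)
}

#' Transcript-protein fold-change correlation
#'
#' Pearson correlation of transcript versus protein log2 fold changes over
#' complete pairs.
#'
#' @param transcript_log2fc,protein_log2fc numeric vectors.
#' @return list with `r`, `r_squared`, `n`.
#' @export
correlate_pairs <- function(transcript_log2fc, protein_log2fc) {
  ok <- stats::complete.cases(transcript_log2fc, protein_log2fc)
  x <- transcript_log2fc[ok]; y <- protein_log2fc[ok]
  if (length(x) < 3L) stopf("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("zero variance in fold changes")
  r <- stats::cor(x, y)
  list(r = r, r_squared = r^2, n = length(x))
}
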