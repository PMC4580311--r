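# Peptide-level filtering, protein-ratio computation, Aox1-normalized
# peroxisome-enrichment scoring, and a simple C-terminal PTS1 motif screen.

#' Filter a peptide table by intensity, spectrum, and replicate rules
#'
#' Excludes (1) peptides with ion intensity below `min_intensity`;
#' (2) proteins whose ratio would derive from fewer than `min_peptides`
#' quantifying peptide spectra (after the intensity filter); (3) proteins
#' identified in fewer than `min_replicates` replicates. Every exclusion is
#' logged with its reason.
#'
#' @param records data.frame with columns `peptide`, `protein`,
#'   `replicate`, `intensity`, and any further columns (carried through).
#' @param min_intensity ion-intensity floor (default 300).
#' @param min_peptides minimum quantifying spectra per protein (default 2).
#' @param min_replicates minimum replicates per protein (default 3).
#' @return list: `retained` (surviving records) and `excluded` (records
#'   with a `reason` column).
#' @export
filter_peptides <- function(records, min_intensity = 300,
                            min_peptides = 2L, min_replicates = 3L) {
  if (!nrow(records))
    return(list(retained = records,
                excluded = cbind(records, reason = character(0))))
  reason <- rep(NA_character_, nrow(records))
  low <- records$intensity < min_intensity
  reason[low] <- "intensity_below_threshold"
  keep <- !low
  spec_count <- table(records$protein[keep])
  few_spec <- keep & spec_count[records$protein] < min_peptides
  reason[few_spec & is.na(reason)] <- "single_peptide_spectrum"
  keep <- keep & !few_spec
  rep_count <- tapply(records$replicate[keep], records$protein[keep],
                      function(x) length(unique(x)))
  few_rep <- keep & rep_count[records$protein] < min_replicates
  reason[few_rep & is.na(reason)] <- "too_few_replicates"
  keep <- keep & !few_rep
  excluded <- records[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  list(retained = records[keep, , drop = FALSE], excluded = excluded)
}

#' Protein ratio from peptide log2 ratios
#'
#' Removes outlying peptide log2 ratios (outside median +/- `k` times the
#' interquartile range), averages the rest with the given weights, and
#' tests the mean ratio against 0 with a one-sample t-test (the random
#' protein-ratio distribution is treated as t-distributed).
#'
#' @param peptide_ratios numeric vector of peptide log2 ratios (>= 2).
#' @param weights optional non-negative weights (e.g. inverse variance from
#'   a reporter-intensity noise model); equal by default.
#' @param k IQR multiplier of the outlier fence (default 1.5).
#' @return list: `log2fc` (weighted mean), `p` (t-test p-value, NA if
#'   fewer than 2 ratios survive), `outliers` (indices removed), `n_used`.
#' @export
protein_ratio <- function(peptide_ratios, weights = NULL, k = 1.5) {
  n <- length(peptide_ratios)
  if (n < 2L) stopf("need at least 2 peptide ratios")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0))
    stopf("weights must be non-negative and match the ratios")
  med <- stats::median(peptide_ratios)
  iqr <- stats::IQR(peptide_ratios)
  out_idx <- which(peptide_ratios < med - k * iqr |
                   peptide_ratios > med + k * iqr)
  use <- setdiff(seq_len(n), out_idx)
  r <- peptide_ratios[use]; w <- weights[use]
  log2fc <- sum(w * r) / sum(w)
  p <- if (length(r) >= 2L && stats::sd(r) > 0)
    stats::t.test(r, mu = 0)$p.value
  else if (length(r) >= 2L && all(r == 0)) 1.0
  else NA_real_
  list(log2fc = log2fc, p = p, outliers = out_idx, n_used = length(use))
}

#' Aox1-normalized peroxisome/homogenate enrichment ratios
#'
#' For every protein, the summed peak area over peroxisomal preparations is
#' divided by the summed peak area over homogenate samples; all ratios are
#' then divided by the same ratio of the reference protein, so the
#' reference is exactly 1. Proteins detected only in peroxisomal
#' preparations are flagged `only_in_pex` (reported as `Inf`, printed
#' ">>1"); proteins absent from the peroxisomal preparations get ratio 0.
#'
#' @param records data.frame with columns `protein`, `class`
#'   (`"peroxisome"` or `"homogenate"`), `area` (peak area >= 0).
#' @param reference reference protein id (default `"AOX1"`).
#' @return data.frame: protein, area_pex, area_hom, raw_ratio,
#'   norm_ratio, flag (`finite`, `only_in_pex`, `absent_in_pex`).
#' @export
enrichment_ratios <- function(records, reference = "AOX1") {
  if (!all(c("protein", "class", "area") %in% names(records)))
    stopf("records need columns protein, class, area")
  bad <- setdiff(unique(records$class), c("peroxisome", "homogenate"))
  if (length(bad)) stopf("unknown sample class: %s", paste(bad, collapse = ", "))
  prot <- unique(records$protein)
  sum_by <- function(cls) vapply(prot, function(p)
    sum(records$area[records$protein == p & records$class == cls]), 0)
  pex <- sum_by("peroxisome"); hom <- sum_by("homogenate")
  if (!(reference %in% prot) || pex[reference] <= 0 || hom[reference] <= 0)
    stopf("reference protein '%s' must be quantified in both sample classes",
          reference)
  ref_ratio <- pex[reference] / hom[reference]
  raw <- ifelse(hom > 0, pex / hom, Inf)
  norm <- raw / ref_ratio
  flag <- ifelse(pex <= 0, "absent_in_pex",
          ifelse(hom <= 0, "only_in_pex", "finite"))
  norm[pex <= 0] <- 0
  data.frame(protein = prot, area_pex = unname(pex), area_hom = unname(hom),
             raw_ratio = unname(raw), norm_ratio = unname(norm),
             flag = unname(flag), row.names = NULL, stringsAsFactors = FALSE)
}

# canonical PTS1 tripeptide: [SAC][KRH][LM] at the C-terminus
PTS1_POS1 <- c("S", "A", "C")
PTS1_POS2 <- c("K", "R", "H")
PTS1_POS3 <- c("L", "M")

#' Default twilight-zone and exception tripeptides of the PTS1 screen
#'
#' Near-canonical C-terminal tripeptides scored "twilight", and
#' exceptional tripeptides accepted as matches (Aox1's unusual -ARF tail
#' is experimentally peroxisomal). Configurable in [pts1_screen()].
#' @export
PTS1_TWILIGHT <- c("TKL", "PNL", "SKY", "QKL", "HKL")
#' @rdname PTS1_TWILIGHT
#' @export
PTS1_EXCEPTIONS <- c("ARF")

#' Simple C-terminal PTS1 motif screen
#'
#' Scores the last three residues: `match` if the tripeptide is canonical
#' ([SAC][KRH][LM]) or in the exception list, `twilight` if listed in the
#' twilight table, otherwise `no`. This is a deliberately simple motif
#' screen, not a re-implementation of published machine-learned PTS1
#' predictors.
#'
#' @param sequence_tail C-terminal amino-acid sequence (>= 3 residues;
#'   only the last 3 are scored, the last 12 are reported).
#' @param twilight,exceptions configurable tripeptide tables.
#' @return list: `tail` (up to 12 residues), `tripeptide`, `verdict`.
#' @export
pts1_screen <- function(sequence_tail, twilight = PTS1_TWILIGHT,
                        exceptions = PTS1_EXCEPTIONS) {
  s <- toupper(gsub("[^A-Za-z]", "", sequence_tail))
  if (nchar(s) < 3L) stopf("sequence must have at least 3 residues")
  tri <- substr(s, nchar(s) - 2L, nchar(s))
  aa <- strsplit(tri, "")[[1]]
  canonical <- aa[1] %in% PTS1_POS1 && aa[2] %in% PTS1_POS2 &&
    aa[3] %in% PTS1_POS3
  verdict <- if (canonical || tri %in% exceptions) "match"
             else if (tri %in% twilight) "twilight" else "no"
  list(tail = substr(s, max(1L, nchar(s) - 11L), nchar(s)),
       tripeptide = tri, verdict = verdict)
}
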