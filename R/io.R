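# Typed table I/O for every schema the analysis stages exchange, plus the
# umbrella pipeline runner. One format per role: TSV for tables, CSV for
# MDVs (wide mass-isotopomer columns), JSON for models and reports, YAML
# for run configurations.

#' Column schemas of the exchanged tables
#' @export
TABLE_SCHEMAS <- list(
  rates = c(quantity = "character", value = "numeric", sd = "numeric"),
  transcripts = c(gene = "character", log2fc = "numeric", pval = "numeric"),
  proteins = c(protein = "character", log2fc = "numeric", pval = "numeric",
               consistency = "numeric"),
  peptides = c(peptide = "character", protein = "character",
               replicate = "character", intensity = "numeric",
               area = "numeric", class = "character"),
  composition = c(analyte = "character", value_a = "numeric",
                  value_b = "numeric"),
  fluxes = c(reaction = "character", net = "numeric")
)

#' Read a typed TSV table
#'
#' @param path file path.
#' @param schema one of `names(TABLE_SCHEMAS)` or a named type vector.
#' @return data.frame with typed columns; parse failures are reported with
#'   their row number.
#' @export
read_table <- function(path, schema) {
  if (is.character(schema) && length(schema) == 1L) {
    if (!schema %in% names(TABLE_SCHEMAS))
      stopf("unknown schema '%s'", schema)
    schema <- TABLE_SCHEMAS[[schema]]
  }
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!nrow(df)) {
    warnf("empty table: %s", path)
  }
  miss <- setdiff(names(schema), names(df))
  if (length(miss))
    stopf("%s: missing required column(s): %s", path,
          paste(miss, collapse = ", "))
  for (col in names(schema)) {
    if (schema[[col]] == "numeric" && !is.numeric(df[[col]])) {
      v <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
      if (length(bad))
        stopf("%s: column '%s' unparseable at row(s) %s", path, col,
              paste(utils::head(bad, 5), collapse = ", "))
      df[[col]] <- v
    }
  }
  df$.row <- seq_len(nrow(df)) + ifelse(nrow(df) > 0, 1L, 0L)  # header is row 1
  df
}

#' Write a TSV table
#' @param df data.frame (an internal `.row` column is dropped).
#' @param path output path.
#' @export
write_table <- function(df, path) {
  df <- df[setdiff(names(df), ".row")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an MDV set as wide CSV
#'
#' Columns `fragment_id`, `m0..mk`, `sd0..sdk`; shorter fragments padded
#' with empty cells. Full numeric precision.
#'
#' @param x an [mdv_set()].
#' @param path output path.
#' @export
write_mdv_csv <- function(x, path) {
  kmax <- max(lengths(x$mdvs)) - 1L
  pad <- function(v) c(v, rep(NA_real_, kmax + 1L - length(v)))
  rows <- lapply(names(x$mdvs), function(f) {
    m <- pad(x$mdvs[[f]])
    s <- pad(x$sd[[f]] %||% rep(NA_real_, length(x$mdvs[[f]])))
    stats::setNames(as.list(c(m, s)),
                    c(paste0("m", 0:kmax), paste0("sd", 0:kmax)))
  })
  df <- cbind(data.frame(fragment_id = names(x$mdvs),
                         stringsAsFactors = FALSE),
              do.call(rbind, lapply(rows, as.data.frame)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an MDV set from wide CSV
#' @param path CSV as written by [write_mdv_csv()].
#' @return an [mdv_set()].
#' @export
read_mdv_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"fragment_id" %in% names(df)) stopf("%s: missing fragment_id", path)
  mcols <- grep("^m[0-9]+$", names(df), value = TRUE)
  scols <- grep("^sd[0-9]+$", names(df), value = TRUE)
  mcols <- mcols[order(as.integer(sub("m", "", mcols)))]
  scols <- scols[order(as.integer(sub("sd", "", scols)))]
  mdvs <- list(); sds <- list()
  for (i in seq_len(nrow(df))) {
    m <- as.numeric(df[i, mcols]); m <- m[!is.na(m)]
    s <- as.numeric(df[i, scols]); s <- s[seq_along(m)]
    mdvs[[df$fragment_id[i]]] <- m
    if (!all(is.na(s))) sds[[df$fragment_id[i]]] <- s
  }
  mdv_set(mdvs, sd = if (length(sds)) sds, tol = 1e-6)
}

#' Run the demo analysis pipeline
#'
#' Executes the requested stages on synthetic data generated from the run
#' seed - chemostat physiology, label simulation plus flux recovery on the
#' built-in scrambling toy, omics classification, peroxisome enrichment -
#' and writes every table plus a JSON run report with seeds, file hashes,
#' and package version.
#'
#' @param config list (or path to a YAML file) with `seed` (mandatory),
#'   `out_dir` (mandatory), optional `stages` (subset of
#'   `c("physiology", "fluxes", "omics", "enrichment")`).
#' @return the run report (list), invisibly; written as `report.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stopf("config$seed is mandatory")
  if (is.null(config$out_dir)) stopf("config$out_dir is mandatory")
  stages <- config$stages %||% c("physiology", "fluxes", "omics", "enrichment")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  report <- list(package = "xumpflux",
                 version = as.character(utils::packageVersion("xumpflux")),
                 seed = config$seed, stages = stages, outputs = list())

  if ("physiology" %in% stages) {
    obs <- gen_chemostat_obs(list(seed = config$seed))
    st <- obs$observed
    res <- data.frame(
      quantity = c("D", names(st$q_s), "CER", "OUR", "Y_XS", "closure"),
      value = c(st$D, unname(st$q_s), st$CER, st$OUR,
                biomass_yield(st), reduction_balance(st, warn_open = FALSE)),
      stringsAsFactors = FALSE)
    write_table(res, out("physiology.tsv"))
    report$outputs$physiology <- "physiology.tsv"
  }

  if ("fluxes" %in% stages) {
    net <- toy_scramble_network()
    truth <- toy_scramble_fluxes(f = 0.6)
    lab <- tracer_mixture("S_e")
    fr <- fragment_map(list(A = list(A = 1:2), B = list(B = 1:2)))
    ds <- gen_mdv_dataset(net, truth, list(
      seed = config$seed, sd = 0.004, labeling = lab, fragments = fr))
    meas <- measurement_set(ds$replicates[[1]],
                            rates = data.frame(quantity = "upt", value = 1,
                                               sd = 0.02),
                            labeling = lab, fragments = fr)
    est <- fit_fluxes(net, meas, options = list(
      seed = config$seed, n_starts = 3L,
      constraints = list(fixed = c(upt = 1))))
    tab <- data.frame(reaction = names(est$net), net = unname(est$net),
                      true = unname(truth[names(est$net)]),
                      stringsAsFactors = FALSE)
    write_table(tab, out("fluxes.tsv"))
    write_mdv_csv(ds$replicates[[1]], out("mdvs.csv"))
    report$outputs$fluxes <- c("fluxes.tsv", "mdvs.csv")
    report$flux_ssr <- est$ssr
  }

  if ("omics" %in% stages) {
    om <- gen_omics_tables(list(seed = config$seed))
    adj <- by_adjust(om$transcripts$pval)
    tcall <- call_transcript(om$transcripts$log2fc, adj)
    pcall <- call_protein(om$proteins$log2fc, om$proteins$pval,
                          om$proteins$consistency)
    pairs <- data.frame(gene = om$transcripts$gene,
                        transcript_call = tcall,
                        protein_call = ifelse(pcall == "excluded",
                                              NA_character_, pcall),
                        stringsAsFactors = FALSE)
    cls <- classify_pairs(pairs)
    cor <- correlate_pairs(om$transcripts$log2fc, om$proteins$log2fc)
    write_table(cls$pairs, out("omics_calls.tsv"))
    write_table(data.frame(group = names(cls$counts),
                           n = as.integer(cls$counts)), out("omics_groups.tsv"))
    jsonlite::write_json(cor, out("omics_correlation.json"),
                         auto_unbox = TRUE, digits = NA)
    report$outputs$omics <- c("omics_calls.tsv", "omics_groups.tsv",
                              "omics_correlation.json")
  }

  if ("enrichment" %in% stages) {
    pep <- gen_peptide_table(list(seed = config$seed))
    filt <- filter_peptides(pep$records)
    enr <- enrichment_ratios(filt$retained, reference = "AOX1")
    write_table(enr, out("enrichment.tsv"))
    report$outputs$enrichment <- "enrichment.tsv"
  }

  files <- unlist(report$outputs, use.names = FALSE)
  report$hashes <- as.list(tools::md5sum(file.path(config$out_dir, files)))
  names(report$hashes) <- files
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}
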