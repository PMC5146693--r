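#' Validate pipeline inputs
#'
#' Schema, range and duplicate checks over any combination of summary
#' statistics, genotype dosages and cohort table. Returns a
#' machine-readable error table (zero rows when everything is valid).
#'
#' @param stats optional [summary_stats()] data frame or TSV path.
#' @param geno optional [genotype_dosage()] or dosage TSV path.
#' @param cohort optional cohort data frame or CSV path.
#' @return data frame with columns `input`, `where`, `message`.
#' @export
validate_inputs <- function(stats = NULL, geno = NULL, cohort = NULL) {
  errs <- list()
  add <- function(input, where, message)
    errs[[length(errs) + 1]] <<- data.frame(input = input, where = where,
                                            message = message)
  load_or <- function(x, reader, label) {
    if (is.character(x)) {
      if (!file.exists(x)) {
        add(label, x, "file not readable")
        return(NULL)
      }
      tryCatch(reader(x), error = function(e) {
        add(label, x, conditionMessage(e)); NULL
      })
    } else x
  }

  stats <- load_or(stats, read_summary_stats, "stats")
  if (!is.null(stats)) {
    dup <- stats$snp_id[duplicated(stats$snp_id)]
    for (d in unique(dup)) add("stats", d, "duplicated snp_id")
    bad_p <- which(!is.na(stats$pvalue) &
                     (stats$pvalue <= 0 | stats$pvalue > 1))
    for (i in bad_p)
      add("stats", paste0("row ", i), "pvalue outside (0, 1]")
    bad_a <- which(!toupper(stats$effect_allele) %in% c("A", "C", "G", "T") |
                     !toupper(stats$other_allele) %in% c("A", "C", "G", "T"))
    for (i in bad_a)
      add("stats", paste0("row ", i), "allele not in {A, C, G, T}")
    bad_f <- which(!is.na(stats$eaf) & (stats$eaf < 0 | stats$eaf > 1))
    for (i in bad_f)
      add("stats", paste0("row ", i), "eaf outside [0, 1]")
  }

  # the dosage matrix is inspected raw (not via the strict constructor) so
  # each out-of-range cell is reported with its sample and SNP
  geno <- load_or(geno, read_dosage_raw, "geno")
  if (!is.null(geno)) {
    if (inherits(geno, "genotype_dosage"))
      geno <- list(dosage = geno$dosage, map = geno$map)
    bad <- which(!is.na(geno$dosage) &
                   (geno$dosage < 0 | geno$dosage > 2), arr.ind = TRUE)
    for (i in seq_len(nrow(bad)))
      add("geno",
          paste0("sample ", rownames(geno$dosage)[bad[i, 1]], ", snp ",
                 colnames(geno$dosage)[bad[i, 2]]),
          "dosage outside [0, 2]")
    dup <- geno$map$snp_id[duplicated(geno$map$snp_id)]
    for (d in unique(dup)) add("geno", d, "duplicated snp_id")
  }

  cohort <- load_or(cohort, read_cohort, "cohort")
  if (!is.null(cohort)) {
    bad_t <- which(cohort$exit_age <= cohort$entry_age)
    for (i in bad_t)
      add("cohort", paste0("row ", i), "exit_age <= entry_age")
    bad_e <- which(!cohort$event %in% c("chd", "death_other", "censored"))
    for (i in bad_e)
      add("cohort", paste0("row ", i), "unknown event label")
    dup <- cohort$sample_id[duplicated(cohort$sample_id)]
    for (d in unique(dup)) add("cohort", d, "duplicated sample_id")
  }

  if (length(errs) == 0)
    return(data.frame(input = character(0), where = character(0),
                      message = character(0)))
  do.call(rbind, errs)
}

# raw (non-validating) dosage TSV reader used only by validate_inputs
read_dosage_raw <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("snp_id", "chrom", "pos", "counted_allele", "other_allele")
  if (!all(meta %in% names(x)))
    stop_grs("dosage TSV lacks column(s): ",
             paste(setdiff(meta, names(x)), collapse = ", "))
  samples <- setdiff(names(x), meta)
  dos <- t(as.matrix(x[, samples, drop = FALSE]))
  colnames(dos) <- x$snp_id
  list(dosage = dos, map = x[, meta])
}
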