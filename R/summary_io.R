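# Reading, validating and writing GWAS summary statistics and LD tables.

CANONICAL_COLS <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                    "beta", "se", "pval", "eaf", "n")
REQUIRED_COLS <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                   "beta", "se", "pval")
MISSING_TOKENS <- c("NA", "", ".")

#' Construct a GWAS summary dataset
#'
#' Bundles a per-SNP summary-statistic table with trait metadata. Each row
#' holds one SNP's association with the trait: effect size `beta` per copy of
#' `effect_allele` (log-odds for a binary outcome, SD units for a
#' quantitative exposure), its standard error, p-value, effect-allele
#' frequency and sample size.
#'
#' @param records data.frame with columns `rsid`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pval`, and optionally
#'   `eaf` and `n`.
#' @param trait_id character trait label.
#' @param trait_type `"exposure"` or `"outcome"`.
#' @param default_n fallback sample size used where `n` is missing.
#' @return An object of class `summary_dataset`.
#' @export
summary_dataset <- function(records, trait_id, trait_type = c("exposure", "outcome"),
                            default_n = NA_integer_) {
  trait_type <- match.arg(trait_type)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"eaf" %in% names(records)) records$eaf <- NA_real_
  if (!"n" %in% names(records)) records$n <- as.integer(default_n)
  records$n[is.na(records$n)] <- as.integer(default_n)
  missing_cols <- setdiff(REQUIRED_COLS, names(records))
  if (length(missing_cols) > 0) {
    stop("summary dataset records lack required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(records$rsid)) {
    stop("duplicate rsid values in dataset '", trait_id, "'", call. = FALSE)
  }
  records <- records[CANONICAL_COLS]
  rownames(records) <- NULL
  structure(
    list(trait_id = trait_id, trait_type = trait_type,
         records = records, default_n = as.integer(default_n)),
    class = "summary_dataset"
  )
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf("<summary_dataset> %s (%s): %d SNPs\n",
              x$trait_id, x$trait_type, nrow(x$records)))
  invisible(x)
}

#' Number of SNP records in a summary dataset
#' @param x a `summary_dataset`.
#' @return integer record count.
#' @export
n_snps <- function(x) nrow(x$records)

validate_records <- function(df) {
  # Returns logical keep-vector plus per-reason drop counts; bad rows are
  # dropped, not fatal, so a mostly-clean file still loads.
  reasons <- character(nrow(df))
  bad_allele <- !(df$effect_allele %in% names(DNA_COMPLEMENT)) |
    !(df$other_allele %in% names(DNA_COMPLEMENT))
  reasons[bad_allele] <- "non_acgt_allele"
  same_allele <- !bad_allele & df$effect_allele == df$other_allele
  reasons[same_allele] <- "identical_alleles"
  bad_num <- is.na(df$beta) | is.na(df$se) | is.na(df$pval) |
    is.na(df$pos) | is.na(df$rsid) | df$rsid == ""
  reasons[bad_num & reasons == ""] <- "unparsable"
  bad_se <- !bad_num & df$se <= 0
  reasons[bad_se & reasons == ""] <- "nonpositive_se"
  bad_p <- !bad_num & (df$pval <= 0 | df$pval > 1)
  reasons[bad_p & reasons == ""] <- "pval_out_of_range"
  bad_eaf <- !is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1)
  reasons[bad_eaf & reasons == ""] <- "eaf_out_of_range"
  bad_n <- !is.na(df$n) & df$n <= 0
  reasons[bad_n & reasons == ""] <- "nonpositive_n"
  reasons
}

#' Read GWAS summary statistics from delimited text
#'
#' Loads a tab- or comma-delimited summary-statistics file through a column
#' map, validates each row against the per-SNP invariants (ACGT alleles,
#' `se > 0`, `pval` in (0,1], `eaf` in (0,1) when present), drops invalid
#' rows, and reports the drop counts in a load report attached as the
#' `"load_report"` attribute.
#'
#' @param path file path.
#' @param column_map named character vector mapping canonical field names
#'   (`rsid`, `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`, `se`,
#'   `pval`, `eaf`, `n`) to column names in the file. Defaults to the
#'   identity map over the canonical names.
#' @param trait_id trait label for the resulting dataset.
#' @param trait_type `"exposure"` or `"outcome"`.
#' @param default_n fallback sample size where the `n` column is absent or
#'   missing.
#' @param delim field delimiter; `NULL` (default) sniffs tab vs comma from
#'   the header line.
#' @return A `summary_dataset`; `attr(, "load_report")` holds
#'   `n_input`, `n_kept`, `n_dropped` and a per-reason drop table.
#' @export
read_summary <- function(path, column_map = NULL, trait_id = basename(path),
                         trait_type = c("exposure", "outcome"),
                         default_n = NA_integer_, delim = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header_line <- readLines(path, n = 1L)
  if (is.null(delim)) {
    delim <- if (grepl("\t", header_line)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, na.strings = MISSING_TOKENS,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "")
  if (is.null(column_map)) {
    column_map <- stats::setNames(CANONICAL_COLS, CANONICAL_COLS)
  }
  unknown <- setdiff(names(column_map), CANONICAL_COLS)
  if (length(unknown) > 0) {
    stop("column_map has unknown field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  required_map <- column_map[names(column_map) %in% REQUIRED_COLS]
  if (!all(REQUIRED_COLS %in% names(column_map))) {
    stop("column_map must map required field(s): ",
         paste(setdiff(REQUIRED_COLS, names(column_map)), collapse = ", "),
         call. = FALSE)
  }
  absent <- required_map[!(required_map %in% names(raw))]
  if (length(absent) > 0) {
    stop("mapped column(s) not in file header: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  get_col <- function(field) {
    if (!(field %in% names(column_map))) return(rep(NA_character_, nrow(raw)))
    col <- column_map[[field]]
    if (!(col %in% names(raw))) return(rep(NA_character_, nrow(raw)))
    raw[[col]]
  }
  df <- data.frame(
    rsid = get_col("rsid"),
    chrom = get_col("chrom"),
    pos = suppressWarnings(as.integer(get_col("pos"))),
    effect_allele = toupper(get_col("effect_allele")),
    other_allele = toupper(get_col("other_allele")),
    beta = suppressWarnings(as.numeric(get_col("beta"))),
    se = suppressWarnings(as.numeric(get_col("se"))),
    pval = suppressWarnings(as.numeric(get_col("pval"))),
    eaf = suppressWarnings(as.numeric(get_col("eaf"))),
    n = suppressWarnings(as.integer(get_col("n"))),
    stringsAsFactors = FALSE
  )
  if (!("eaf" %in% names(column_map)) ||
      !(column_map[["eaf"]] %in% names(raw))) {
    warning("no eaf column mapped for '", trait_id,
            "'; eaf will be missing on all records", call. = FALSE)
  }
  reasons <- validate_records(df)
  keep <- reasons == ""
  if (!any(keep)) stop("zero parsable rows in ", path, call. = FALSE)
  # p-vs-z consistency is a warning, never a drop: rounded p-values are common.
  z_implied <- z_pval(df$beta[keep], df$se[keep])
  inconsistent <- abs(log10(z_implied) - log10(df$pval[keep])) > 1
  if (any(inconsistent, na.rm = TRUE)) {
    warning(sum(inconsistent, na.rm = TRUE),
            " row(s) have pval inconsistent with |beta/se| beyond 10x on the ",
            "log10 scale", call. = FALSE)
  }
  ds <- summary_dataset(df[keep, , drop = FALSE], trait_id = trait_id,
                        trait_type = trait_type, default_n = default_n)
  drop_tab <- table(reasons[!keep])
  attr(ds, "load_report") <- list(
    n_input = nrow(df), n_kept = sum(keep), n_dropped = sum(!keep),
    dropped_by_reason = as.list(drop_tab)
  )
  ds
}

#' Write a summary dataset to tab-delimited text
#'
#' Writes the canonical ten-column layout (`rsid`, `chrom`, `pos`,
#' `effect_allele`, `other_allele`, `beta`, `se`, `pval`, `eaf`, `n`) with
#' `NA` as the missing-value token. `read_summary()` on the written file
#' reproduces the dataset field-for-field.
#'
#' @param ds a non-empty `summary_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(ds, path) {
  stopifnot(inherits(ds, "summary_dataset"))
  if (nrow(ds$records) == 0) {
    stop("refusing to write empty summary dataset", call. = FALSE)
  }
  df <- ds$records
  df$beta <- format(df$beta, digits = 17, trim = TRUE, scientific = NA)
  df$se <- format(df$se, digits = 17, trim = TRUE, scientific = NA)
  df$pval <- format(df$pval, digits = 17, trim = TRUE, scientific = NA)
  df$eaf <- ifelse(is.na(ds$records$eaf), "NA",
                   format(ds$records$eaf, digits = 17, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a pairwise LD table
#'
#' Three-column text (`rsid_a`, `rsid_b`, `r2`), header optional. The table
#' is stored symmetrically; absent pairs are treated as r-squared 0 by
#' [ld_r2()].
#'
#' @param path file path (tab or comma delimited).
#' @return An `ld_table` object.
#' @export
read_ld_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  has_header <- grepl("rsid|snp", tolower(first))
  raw <- utils::read.table(path, header = has_header, sep = delim,
                           stringsAsFactors = FALSE)
  if (ncol(raw) != 3) stop("LD table must have exactly 3 columns", call. = FALSE)
  names(raw) <- c("rsid_a", "rsid_b", "r2")
  raw$r2 <- suppressWarnings(as.numeric(raw$r2))
  bad <- which(is.na(raw$r2) | raw$r2 < 0 | raw$r2 > 1)
  if (length(bad) > 0) {
    stop("r2 outside [0,1] (or unparsable) at row ", bad[1], call. = FALSE)
  }
  ld_table(raw)
}

#' Construct an LD table from pair data
#'
#' @param pairs data.frame with columns `rsid_a`, `rsid_b`, `r2` in `[0,1]`.
#'   Duplicated pairs (in either orientation) with conflicting r-squared are
#'   an error.
#' @return An `ld_table`: a symmetric sparse lookup; missing pairs read as 0.
#' @export
ld_table <- function(pairs = NULL) {
  env <- new.env(parent = emptyenv())
  if (!is.null(pairs) && nrow(pairs) > 0) {
    key <- ifelse(pairs$rsid_a < pairs$rsid_b,
                  paste0(pairs$rsid_a, "\r", pairs$rsid_b),
                  paste0(pairs$rsid_b, "\r", pairs$rsid_a))
    for (i in seq_len(nrow(pairs))) {
      existing <- env[[key[i]]]
      if (!is.null(existing) && existing != pairs$r2[i]) {
        stop("conflicting r2 for pair (", pairs$rsid_a[i], ", ",
             pairs$rsid_b[i], "): ", existing, " vs ", pairs$r2[i],
             call. = FALSE)
      }
      env[[key[i]]] <- pairs$r2[i]
    }
  }
  structure(list(env = env), class = "ld_table")
}

#' Look up pairwise LD
#'
#' @param ld an `ld_table`.
#' @param a,b rsid vectors (recycled to common length).
#' @return numeric r-squared; 1 for `a == b`, 0 for unrecorded pairs.
#' @export
ld_r2 <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_table"))
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  key <- ifelse(a < b, paste0(a, "\r", b), paste0(b, "\r", a))
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (a[i] == b[i]) { out[i] <- 1; next }
    v <- ld$env[[key[i]]]
    out[i] <- if (is.null(v)) 0 else v
  }
  out
}

#' @export
print.ld_table <- function(x, ...) {
  cat(sprintf("<ld_table> %d recorded pairs\n", length(ls(x$env))))
  invisible(x)
}

#' Write an LD table to tab-delimited text
#' @param ld an `ld_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld_table <- function(ld, path) {
  keys <- ls(ld$env)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  df <- data.frame(
    rsid_a = vapply(parts, `[`, "", 1),
    rsid_b = vapply(parts, `[`, "", 2),
    r2 = vapply(keys, function(k) ld$env[[k]], 0),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
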