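#' @importFrom stats pnorm pchisq pt qnorm rnorm runif rbinom quantile
#'   density sd var cor setNames optimise complete.cases
#' @importFrom utils head modifyList
#' @import data.table
NULL

VALID_ALLELES <- c("A", "C", "G", "T")

## delimited reader, gzip-transparent (gz goes through a connection;
## plain files through fread, which also sniffs the delimiter)
read_delim_auto <- function(path) {
  if (grepl("\\.gz$", path)) {
    utils::read.table(gzfile(path), header = TRUE,
                      stringsAsFactors = FALSE)
  } else {
    data.table::fread(path, header = TRUE, data.table = FALSE)
  }
}

#' Default column mapping for GWAS summary-statistics tables
#'
#' Maps the fields of a variant association record to the column names
#' expected in an input table. Override any entry via the `column_map`
#' argument of [read_sumstats()], or supply a YAML file with the same keys.
#'
#' @return Named character vector with entries `snp`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @export
default_column_map <- function() {
  c(snp = "SNP", chrom = "CHR", pos = "POS",
    effect_allele = "EA", other_allele = "OA",
    eaf = "EAF", beta = "BETA", se = "SE", pval = "P", n = "N")
}

#' Positional variant key
#'
#' Builds the `chrom:pos:a1:a2` identifier used for cross-study matching,
#' with the two alleles in lexicographic order so that records describing
#' the same site with swapped effect/other alleles share one key. rsIDs are
#' carried as labels only; identity is positional.
#'
#' @param chrom Chromosome label (character, e.g. `"6"`).
#' @param pos 1-based position (integer).
#' @param a1,a2 The two alleles (single characters in A/C/G/T).
#' @return Character vector of keys.
#' @examples
#' variant_key("1", 100, "G", "A")  # "1:100:A:G"
#' @export
variant_key <- function(chrom, pos, a1, a2) {
  lo <- pmin(a1, a2)
  hi <- pmax(a1, a2)
  paste(chrom, as.integer(pos), lo, hi, sep = ":")
}

## Inverse of variant_key: data.frame(chrom, pos, a1, a2)
parse_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    pos = as.integer(vapply(parts, `[`, "", 2L)),
    a1 = vapply(parts, `[`, "", 3L),
    a2 = vapply(parts, `[`, "", 4L),
    stringsAsFactors = FALSE
  )
}

#' Ambiguous palindromic SNP test
#'
#' A/T and C/G variants cannot be strand-resolved from alleles alone; they
#' are treated as ambiguous when the effect-allele frequency is missing or
#' lies within `maf_window` of 0.5. With the default window of 0.08,
#' palindromes with minor-allele frequency in (0.42, 0.5] are ambiguous and
#' removed from instrument lists.
#'
#' @param effect_allele,other_allele Allele vectors.
#' @param eaf Effect-allele frequency (may be `NA`).
#' @param maf_window Half-width of the ambiguity window around 0.5.
#' @return Logical vector.
#' @export
is_ambiguous_palindromic <- function(effect_allele, other_allele, eaf,
                                     maf_window = 0.08) {
  pal <- (effect_allele == "A" & other_allele == "T") |
    (effect_allele == "T" & other_allele == "A") |
    (effect_allele == "C" & other_allele == "G") |
    (effect_allele == "G" & other_allele == "C")
  near_half <- is.na(eaf) | abs(eaf - 0.5) < maf_window
  pal & near_half
}

new_sumstats <- function(data, study_label, trait_label,
                         trait_type = c("quantitative", "binary")) {
  trait_type <- match.arg(trait_type)
  structure(
    list(study_label = study_label, trait_label = trait_label,
         trait_type = trait_type, data = data),
    class = "sumstats"
  )
}

#' Construct a summary-statistics object from a data frame
#'
#' Validates one association record per variant: alleles in A/C/G/T and
#' distinct (indels and multi-allelic codes are rejected), `se > 0`, `pval`
#' in (0, 1], `eaf` in \[0, 1\] or missing. Rows violating an invariant are
#' dropped with a warning giving per-reason counts; duplicate positional
#' keys keep the smallest p-value.
#'
#' @param df Data frame with columns `snp`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval`, `n` (`eaf`/`n` optional).
#' @param study_label,trait_label Labels carried through to results.
#' @param trait_type `"quantitative"` (betas in SD units) or `"binary"`
#'   (betas on the log-odds scale).
#' @return A `sumstats` object whose `$data` has one row per positional key,
#'   with the key in column `key`.
#' @export
as_sumstats <- function(df, study_label = "study", trait_label = "trait",
                        trait_type = "quantitative") {
  need <- c("snp", "chrom", "pos", "effect_allele", "other_allele",
            "beta", "se", "pval")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("no rows in summary statistics input")
  if (!"eaf" %in% names(df)) df$eaf <- NA_real_
  if (!"n" %in% names(df)) df$n <- NA_integer_

  df <- data.frame(
    snp = as.character(df$snp), chrom = as.character(df$chrom),
    pos = as.integer(df$pos),
    effect_allele = toupper(as.character(df$effect_allele)),
    other_allele = toupper(as.character(df$other_allele)),
    eaf = as.numeric(df$eaf), beta = as.numeric(df$beta),
    se = as.numeric(df$se), pval = as.numeric(df$pval),
    n = as.numeric(df$n), stringsAsFactors = FALSE
  )

  bad <- list(
    allele = !(df$effect_allele %in% VALID_ALLELES &
                 df$other_allele %in% VALID_ALLELES &
                 df$effect_allele != df$other_allele),
    se = !is.finite(df$se) | df$se <= 0,
    pval = !is.finite(df$pval) | df$pval <= 0 | df$pval > 1,
    beta = !is.finite(df$beta),
    eaf = !is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1),
    pos = is.na(df$pos) | df$pos < 1
  )
  drop <- Reduce(`|`, bad)
  if (any(drop)) {
    counts <- vapply(bad, function(b) sum(b & drop), 0L)
    counts <- counts[counts > 0L]
    warning(sprintf("dropped %d invalid row(s): %s", sum(drop),
                    paste(names(counts), counts, sep = "=", collapse = ", ")),
            call. = FALSE)
    df <- df[!drop, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no valid rows after filtering")

  df$key <- variant_key(df$chrom, df$pos, df$effect_allele, df$other_allele)
  if (anyDuplicated(df$key)) {
    df <- df[order(df$key, df$pval), , drop = FALSE]
    df <- df[!duplicated(df$key), , drop = FALSE]
  }
  rownames(df) <- NULL
  new_sumstats(df, study_label, trait_label, trait_type)
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a whitespace-, comma- or tab-delimited table (gzip-transparent)
#' with a header, renames columns according to `column_map`, and validates
#' records via [as_sumstats()].
#'
#' @param path File path.
#' @param column_map Named character vector overriding entries of
#'   [default_column_map()], or a path to a YAML file of such entries.
#' @inheritParams as_sumstats
#' @return A `sumstats` object.
#' @export
read_sumstats <- function(path, column_map = NULL, study_label = "study",
                          trait_label = "trait",
                          trait_type = "quantitative") {
  cmap <- default_column_map()
  if (!is.null(column_map)) {
    if (is.character(column_map) && length(column_map) == 1L &&
        file.exists(column_map) && is.null(names(column_map))) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("the 'yaml' package is required to read a column-map file")
      column_map <- unlist(yaml::read_yaml(column_map))
    }
    cmap[names(column_map)] <- column_map
  }
  dt <- read_delim_auto(path)
  if (nrow(dt) == 0L) stop("empty summary statistics file: ", path)
  mandatory <- setdiff(names(cmap), c("eaf", "n"))
  for (field in names(cmap)) {
    col <- cmap[[field]]
    if (!col %in% names(dt)) {
      if (field %in% mandatory)
        stop("missing mandatory column '", col, "' in ", path)
      dt[[field]] <- NA
    } else {
      names(dt)[names(dt) == col] <- field
    }
  }
  as_sumstats(dt, study_label, trait_label, trait_type)
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> %s / %s (%s): %d variants\n", x$study_label,
              x$trait_label, x$trait_type, nrow(x$data)))
  invisible(x)
}

#' Write a results table deterministically
#'
#' Writes a tab-separated file with a header. Rows are sorted by
#' `protein_id`, then `outcome_label` (when present), then `method`/`key`,
#' so the same rows in any input order produce a byte-identical file.
#' Floats are rendered with 6 significant digits.
#'
#' @param rows Data frame of result records sharing one schema.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_results_table <- function(rows, path) {
  rows <- as.data.frame(rows)
  ord_cols <- intersect(c("protein_id", "outcome_label", "method", "key"),
                        names(rows))
  if (length(ord_cols) > 0L && nrow(rows) > 0L)
    rows <- rows[do.call(order, unname(as.list(rows[ord_cols]))), ,
                 drop = FALSE]
  num <- vapply(rows, is.double, TRUE)
  rows[num] <- lapply(rows[num], function(x) signif(x, 6L))
  data.table::fwrite(rows, file = path, sep = "\t", quote = FALSE,
                     na = "NA", scipen = 0)
  invisible(path)
}
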