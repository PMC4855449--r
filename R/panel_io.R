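# Reading, validating and writing parental frequency panels, genotype
# matrices and estimate tables.

PANEL_COLUMNS <- c("snp_id", "chrom", "pos", "allele1", "allele2",
                   "p_eu", "p_ai", "p_af")
PANEL_OPTIONAL <- c("replicate_discordance", "set_label")

#' Validate a data frame as a parental allele-frequency panel
#'
#' A parental panel holds, per SNP, the allele-1 frequency in the three
#' reference (ancestral) populations: European (`p_eu`), American Indian
#' (`p_ai`) and African (`p_af`). These frequencies are the fixed, known
#' quantities of the supervised ancestry likelihood; the panel also fixes
#' the allele orientation (which allele is "allele 1") for all genotype
#' input.
#'
#' Records are sorted by (chromosome, position); duplicate coordinates,
#' frequencies outside \[0, 1\] and identical allele pairs are rejected.
#'
#' @param x data frame with columns `snp_id`, `chrom`, `pos`, `allele1`,
#'   `allele2`, `p_eu`, `p_ai`, `p_af` and optionally
#'   `replicate_discordance`, `set_label`.
#' @return the validated, position-sorted panel with class
#'   `parental_panel`.
#' @export
as_parental_panel <- function(x) {
  if (!is.data.frame(x)) stop("panel must be a data frame")
  missing_cols <- setdiff(PANEL_COLUMNS, names(x))
  if (length(missing_cols) > 0) {
    stop("panel is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (nrow(x) == 0) stop("panel has no SNPs")
  x$chrom <- as.character(x$chrom)
  for (col in c("p_eu", "p_ai", "p_af")) {
    p <- x[[col]]
    if (!is.numeric(p) || anyNA(p)) {
      stop("column '", col, "' must be numeric with no missing values")
    }
    bad <- which(p < 0 | p > 1)
    if (length(bad) > 0) {
      stop(sprintf("column '%s' outside [0, 1] at row %d (value %g)",
                   col, bad[1], p[bad[1]]))
    }
  }
  same <- which(as.character(x$allele1) == as.character(x$allele2))
  if (length(same) > 0) {
    stop(sprintf("allele1 equals allele2 at row %d (snp '%s')",
                 same[1], x$snp_id[same[1]]))
  }
  if (anyDuplicated(x$snp_id) > 0) {
    stop("duplicate snp_id: ", x$snp_id[anyDuplicated(x$snp_id)])
  }
  x <- x[order(chrom_rank(x$chrom), x$pos), , drop = FALSE]
  dup <- which(duplicated(x[c("chrom", "pos")]))
  if (length(dup) > 0) {
    stop(sprintf("duplicate (chrom, pos) = (%s, %s)",
                 x$chrom[dup[1]], format(x$pos[dup[1]], scientific = FALSE)))
  }
  rownames(x) <- NULL
  class(x) <- c("parental_panel", "data.frame")
  x
}

#' Read a parental frequency panel from a tab-separated file
#'
#' @param path path to a TSV with the columns of [as_parental_panel()].
#' @param dialect optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(p_eu = "CEU_freq", p_af = "YRI_LWK_freq")`, so externally produced
#'   AIM tables can be ingested without editing.
#' @param sep field separator, tab by default.
#' @return a `parental_panel`.
#' @export
read_panel <- function(path, dialect = NULL, sep = "\t") {
  if (!file.exists(path)) stop("panel file not found: ", path)
  x <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      file_col <- dialect[[canon]]
      if (!file_col %in% names(x)) {
        stop("dialect names column '", file_col, "' not present in file")
      }
      names(x)[names(x) == file_col] <- canon
    }
  }
  missing_cols <- setdiff(PANEL_COLUMNS, names(x))
  if (length(missing_cols) > 0) {
    stop("panel file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  as_parental_panel(x)
}

#' Write a parental panel to a tab-separated file
#'
#' @param panel a `parental_panel`.
#' @param path output path.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "parental_panel"))
  utils::write.table(panel, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Merge allele-1 frequencies from two reference samples of one ancestry
#'
#' When one ancestral population is represented by two reference samples
#' (e.g. two African reference groups), the allele-1 frequency used for
#' that ancestry is the unweighted mean where the SNP was typed in both
#' samples, and the single available value where it was typed in only one.
#' A provenance flag records which case applied.
#'
#' @param freqs_a,freqs_b data frames with columns `snp_id`, `p` and
#'   optionally `allele1`, `allele2` (used to detect orientation
#'   conflicts for shared SNPs).
#' @return data frame with `snp_id`, `p` (merged frequency) and `source`
#'   (`"both"`, `"a_only"` or `"b_only"`), plus allele columns when
#'   present in either input.
#' @export
average_reference_freqs <- function(freqs_a, freqs_b) {
  for (f in list(freqs_a, freqs_b)) {
    if (!all(c("snp_id", "p") %in% names(f))) {
      stop("each frequency table needs columns 'snp_id' and 'p'")
    }
  }
  has_alleles <- all(c("allele1", "allele2") %in% names(freqs_a)) &&
    all(c("allele1", "allele2") %in% names(freqs_b))
  m <- merge(freqs_a, freqs_b, by = "snp_id", all = TRUE,
             suffixes = c("_a", "_b"))
  if (has_alleles) {
    shared <- !is.na(m$p_a) & !is.na(m$p_b)
    conflict <- shared &
      (m$allele1_a != m$allele1_b | m$allele2_a != m$allele2_b)
    if (any(conflict)) {
      stop("allele orientation conflict for shared SNP '",
           m$snp_id[which(conflict)[1]], "'")
    }
  }
  p <- ifelse(is.na(m$p_a), m$p_b,
              ifelse(is.na(m$p_b), m$p_a, (m$p_a + m$p_b) / 2))
  src <- ifelse(is.na(m$p_a), "b_only",
                ifelse(is.na(m$p_b), "a_only", "both"))
  out <- data.frame(snp_id = m$snp_id, p = p, source = src,
                    stringsAsFactors = FALSE)
  if (has_alleles) {
    out$allele1 <- ifelse(is.na(m$allele1_a), m$allele1_b, m$allele1_a)
    out$allele2 <- ifelse(is.na(m$allele2_a), m$allele2_b, m$allele2_a)
  }
  out
}

#' Construct a genotype matrix aligned to a panel
#'
#' @param dosages integer matrix, individuals in rows and SNPs in columns,
#'   holding the count of panel allele 1 (0, 1, 2) or `NA` for missing.
#'   Columns must follow panel order.
#' @param panel the `parental_panel` the columns align to.
#' @param sample_ids individual identifiers; defaults to the row names.
#' @return an object of class `genotype_matrix`: a list with elements
#'   `dosages`, `sample_ids` and `panel`.
#' @export
genotype_matrix <- function(dosages, panel, sample_ids = rownames(dosages)) {
  stopifnot(inherits(panel, "parental_panel"))
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != nrow(panel)) {
    stop("dosage matrix has ", ncol(dosages), " columns but panel has ",
         nrow(panel), " SNPs")
  }
  if (is.null(sample_ids)) sample_ids <- sprintf("ind%04d", seq_len(nrow(dosages)))
  vals <- dosages[!is.na(dosages)]
  if (length(vals) > 0 && !all(vals %in% c(0, 1, 2))) {
    bad <- which(!is.na(dosages) & !(dosages %in% c(0, 1, 2)),
                 arr.ind = TRUE)[1, ]
    stop(sprintf("dosage %g for sample '%s' at SNP '%s' is not in {0, 1, 2, NA}",
                 dosages[bad[1], bad[2]], sample_ids[bad[1]],
                 panel$snp_id[bad[2]]))
  }
  dimnames(dosages) <- list(sample_ids, panel$snp_id)
  structure(list(dosages = dosages, sample_ids = sample_ids, panel = panel),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "individuals x",
      ncol(x$dosages), "SNPs;",
      sum(is.na(x$dosages)), "missing calls\n")
  invisible(x)
}

#' Read an allele-1 dosage matrix from a tab-separated file
#'
#' The file has a header `sample_id` followed by one column per SNP id;
#' body rows hold dosages of the panel's allele 1. Columns are reordered
#' to panel order; panel SNPs absent from the file become missing for all
#' samples (a message reports the count); file columns not in the panel
#' are dropped.
#'
#' @param path path to the genotype TSV.
#' @param panel `parental_panel` defining SNP order and allele orientation.
#' @param missing_token string encoding a missing genotype (default `"NA"`).
#' @return a `genotype_matrix`.
#' @export
read_genotypes_tsv <- function(path, panel, missing_token = "NA") {
  stopifnot(inherits(panel, "parental_panel"))
  if (!file.exists(path)) stop("genotype file not found: ", path)
  x <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character",
                         na.strings = NULL)
  if (names(x)[1] != "sample_id") {
    stop("first column of a genotype TSV must be 'sample_id'")
  }
  sample_ids <- x$sample_id
  snp_cols <- setdiff(names(x), "sample_id")
  extra <- setdiff(snp_cols, panel$snp_id)
  if (length(extra) > 0) {
    message(length(extra), " genotype column(s) not in the panel dropped")
  }
  absent <- setdiff(panel$snp_id, snp_cols)
  if (length(absent) > 0) {
    message(length(absent), " panel SNP(s) absent from the genotype file; ",
            "set to missing")
  }
  d <- matrix(NA_integer_, nrow = length(sample_ids), ncol = nrow(panel),
              dimnames = list(sample_ids, panel$snp_id))
  for (s in intersect(panel$snp_id, snp_cols)) {
    v <- x[[s]]
    v[v == missing_token] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & (is.na(num) | !(num %in% c(0, 1, 2))))
    if (length(bad) > 0) {
      stop(sprintf("invalid dosage '%s' for sample '%s' at SNP '%s'",
                   v[bad[1]], sample_ids[bad[1]], s))
    }
    d[, s] <- as.integer(num)
  }
  genotype_matrix(d, panel, sample_ids)
}

#' Write a genotype matrix to a tab-separated file
#'
#' @param gm a `genotype_matrix`.
#' @param path output path.
#' @param missing_token string written for missing genotypes.
#' @export
write_genotypes_tsv <- function(gm, path, missing_token = "NA") {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosages
  out <- data.frame(sample_id = gm$sample_ids, d, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = missing_token)
  invisible(path)
}

#' Extract allele-1 dosages from a VCF, aligned to a panel
#'
#' VCF sites are matched to the panel by (chromosome, position). A site is
#' used only if it is biallelic and its REF/ALT pair equals the panel's
#' allele pair; the dosage counted is of the panel's allele 1 (which may
#' be REF or ALT). Mismatching sites are skipped with a message. Missing
#' and half-called genotypes become missing. Panel SNPs without a matching
#' site are missing for all samples.
#'
#' @param path path to a VCF file with GT fields.
#' @param panel `parental_panel` giving coordinates and allele orientation.
#' @return a `genotype_matrix`.
#' @export
dosages_from_vcf <- function(path, panel) {
  stopifnot(inherits(panel, "parental_panel"))
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || ncol(gt) == 0) stop("VCF has no genotype (GT) data")
  samples <- colnames(gt)

  key_vcf <- paste(fix$CHROM, fix$POS)
  key_panel <- paste(panel$chrom, format(panel$pos, scientific = FALSE,
                                         trim = TRUE))
  d <- matrix(NA_integer_, nrow = length(samples), ncol = nrow(panel),
              dimnames = list(samples, panel$snp_id))
  matched <- 0L
  skipped <- 0L
  for (j in seq_len(nrow(panel))) {
    i <- match(key_panel[j], key_vcf)
    if (is.na(i)) next
    ref <- fix$REF[i]
    alt <- fix$ALT[i]
    if (grepl(",", alt, fixed = TRUE) ||
        !setequal(c(ref, alt), c(panel$allele1[j], panel$allele2[j]))) {
      skipped <- skipped + 1L
      next
    }
    allele1_code <- if (ref == panel$allele1[j]) "0" else "1"
    gts <- gt[i, ]
    toks <- strsplit(gts, "[/|]")
    d[, j] <- vapply(toks, function(tk) {
      if (length(tk) != 2 || any(tk == ".") || any(is.na(tk))) {
        return(NA_integer_)
      }
      sum(tk == allele1_code)
    }, integer(1))
    matched <- matched + 1L
  }
  if (skipped > 0) {
    message(skipped, " VCF site(s) skipped: allele pair does not match the panel")
  }
  if (matched == 0L) stop("no VCF site matches the panel (empty overlap)")
  genotype_matrix(d, panel, samples)
}

#' Write admixture estimates to a tab-separated file
#'
#' Columns: `sample_id`, `n_snps_used`, `m_eu`, `m_ai`, `m_af`, `se_eu`,
#' `se_ai`, `se_af`, `cov_eu_ai`. Values round-trip through
#' [read_estimates()] at better than 1e-6.
#'
#' @param estimates data frame of estimates as returned by
#'   [estimate_admixture()].
#' @param path output path.
#' @export
write_estimates <- function(estimates, path) {
  cols <- c("sample_id", "n_snps_used", "m_eu", "m_ai", "m_af",
            "se_eu", "se_ai", "se_af", "cov_eu_ai")
  if (nrow(estimates) > 0) {
    missing_cols <- setdiff(cols, names(estimates))
    if (length(missing_cols) > 0) {
      stop("estimates are missing column(s): ",
           paste(missing_cols, collapse = ", "))
    }
  }
  out <- if (nrow(estimates) == 0) {
    as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
  } else {
    estimates[cols]
  }
  utils::write.table(format(out, digits = 10, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an estimates table written by [write_estimates()]
#'
#' @param path path to the estimates TSV.
#' @return data frame with the columns of [write_estimates()].
#' @export
read_estimates <- function(path) {
  if (!file.exists(path)) stop("estimates file not found: ", path)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
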