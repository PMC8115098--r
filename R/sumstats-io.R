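## Reading, validating and writing GWAS summary-statistics tables.

#' Default mapping from canonical column names to file header names
#'
#' The canonical columns are \code{SNP} (variant ID), \code{CHR}, \code{POS}
#' (1-based), \code{A1} (effect allele), \code{A2} (other allele), \code{EAF}
#' (effect-allele frequency), \code{BETA}, \code{SE}, \code{P}, \code{N}.
#' Summary files in the wild use heterogeneous headers; pass a modified map
#' to [readSumstats()] to accommodate them.
#'
#' @return Named character vector, canonical name -> file column name.
#' @export
defaultColumnMap <- function() {
  setNames(SUMSTATS_COLS, SUMSTATS_COLS)
}

## Row-level validation. Returns list(keep = data.table, drops = named int).
## A row is attributed to the FIRST rule that rejects it.
.validate_rows <- function(dt, p_tol = 0.10) {
  dt$A1 <- toupper(dt$A1)
  dt$A2 <- toupper(dt$A2)

  underflow <- !is.na(dt$P) & dt$P == 0
  dt$P[underflow] <- .Machine$double.xmin
  dt$p_underflow <- underflow

  bases <- c("A", "C", "G", "T")
  rules <- list(
    bad_alleles = !(dt$A1 %in% bases) | !(dt$A2 %in% bases) | dt$A1 == dt$A2,
    bad_se = is.na(dt$SE) | dt$SE <= 0,
    bad_p = is.na(dt$P) | dt$P <= 0 | dt$P > 1,
    bad_eaf = !is.na(dt$EAF) & (dt$EAF < 0 | dt$EAF > 1),
    bad_n = is.na(dt$N) | dt$N <= 0,
    bad_beta = is.na(dt$BETA)
  )
  ## beta/se and p must agree with the two-sided normal approximation;
  ## compare on the log scale so tiny p-values are handled stably.
  ok_so_far <- !Reduce(`|`, rules)
  z <- abs(dt$BETA / dt$SE)
  logp_implied <- log(2) + pnorm(z, lower.tail = FALSE, log.p = TRUE)
  incons <- rep(FALSE, nrow(dt))
  chk <- ok_so_far & !dt$p_underflow
  incons[chk] <- abs(log(dt$P[chk]) - logp_implied[chk]) > -log1p(-p_tol)
  rules$inconsistent_p <- incons

  drop <- rep(FALSE, nrow(dt))
  drops <- integer(length(rules))
  names(drops) <- names(rules)
  for (r in names(rules)) {
    hit <- rules[[r]] & !drop
    drops[[r]] <- sum(hit)
    drop <- drop | hit
  }
  list(keep = dt[!drop, , drop = FALSE], drops = drops)
}

#' Read a GWAS summary-statistics file
#'
#' Reads a tab-delimited (optionally gzipped) summary table, maps its columns
#' to the canonical set, upper-cases alleles, replaces p-values of exactly 0
#' by the smallest positive double (flagged in the \code{p_underflow}
#' column), and drops rows violating the record invariants (invalid alleles,
#' non-positive SE, p outside (0,1], allele frequency outside [0,1],
#' non-positive N, or a p-value inconsistent with \code{beta/se} under the
#' two-sided normal approximation at relative tolerance \code{p_tol}).
#' Dropped rows are counted per rule, attributing each row to the first rule
#' that rejects it.
#'
#' @param path File path.
#' @param meta A [StudyMeta-class] describing the study.
#' @param column_map Named character vector mapping canonical names to the
#'   file's header names; see [defaultColumnMap()].
#' @param p_tol Relative tolerance for the beta/se vs p consistency check.
#' @return A [GwasSumstats-class].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' sim <- simulateIVDataset(simTruth(seed = 1))
#' writeSumstats(sim$exposure, tf)
#' ss <- readSumstats(tf, studyMetaOf(sim$exposure))
#' nrow(variants(ss))
#' @export
readSumstats <- function(path, meta = studyMeta("trait"),
                         column_map = defaultColumnMap(), p_tol = 0.10) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", ""), data.table = FALSE,
                          showProgress = FALSE)
  if (nrow(dt) == 0L && ncol(dt) == 0L) stop("empty summary-statistics file: ", path)
  cmap <- modifyList(as.list(defaultColumnMap()), as.list(column_map))
  miss <- setdiff(unlist(cmap), names(dt))
  if (length(miss))
    stop("mapped columns absent from header: ", paste(miss, collapse = ", "))
  out <- dt[, unlist(cmap)[SUMSTATS_COLS], drop = FALSE]
  names(out) <- SUMSTATS_COLS
  out$SNP <- as.character(out$SNP)
  out$CHR <- as.character(out$CHR)
  out$POS <- as.integer(out$POS)
  for (col in c("EAF", "BETA", "SE", "P", "N"))
    out[[col]] <- as.numeric(out[[col]])
  v <- .validate_rows(out, p_tol = p_tol)
  new("GwasSumstats", variants = v$keep, meta = meta, dropCounts = v$drops)
}

#' Write a summary-statistics table
#'
#' Writes tab-delimited text with the canonical header. Numeric fields are
#' serialized at full double precision so that
#' \code{readSumstats(writeSumstats(x))} restores the records exactly;
#' missing allele frequencies are written as \code{NA}.
#'
#' @param x A [GwasSumstats-class] or a data.frame in canonical columns.
#' @param path Output path (a \code{.gz} suffix compresses).
#' @return \code{path}, invisibly.
#' @export
writeSumstats <- function(x, path) {
  df <- if (is(x, "GwasSumstats")) x@variants else as.data.frame(x)
  miss <- setdiff(SUMSTATS_COLS, names(df))
  if (length(miss))
    stop("missing canonical columns: ", paste(miss, collapse = ", "))
  out <- df[, SUMSTATS_COLS, drop = FALSE]
  for (col in c("EAF", "BETA", "SE", "P", "N")) {
    v <- sprintf("%.17g", out[[col]])
    v[is.na(out[[col]])] <- "NA"
    out[[col]] <- v
  }
  ok <- tryCatch({
    data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA",
                       compress = if (grepl("\\.gz$", path)) "gzip" else "none")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write to path: ", path)
  invisible(path)
}

#' Clean ("munge") a summary table for genome-wide moment analyses
#'
#' Standardised pre-processing in the LD-score-regression tradition: removes
#' strand-ambiguous (palindromic, A/T or C/G) SNPs and SNPs with minor-allele
#' frequency below \code{maf_min}; SNPs whose association chi-square
#' \eqn{(\beta/se)^2} exceeds \code{chi2_cap} are flagged in the
#' \code{chi2_capped} column (never rescaled or dropped). Idempotent.
#'
#' @param x A [GwasSumstats-class].
#' @param maf_min Minimum minor-allele frequency (default 0.01). SNPs with
#'   missing EAF are retained.
#' @param chi2_cap Chi-square flag threshold (default 80).
#' @return A [GwasSumstats-class] whose \code{dropCounts} holds the
#'   per-filter tallies of this munge step.
#' @export
mungeSumstats <- function(x, maf_min = 0.01, chi2_cap = 80) {
  stopifnot(is(x, "GwasSumstats"))
  df <- x@variants
  pal <- isPalindromic(df$A1, df$A2)
  maf <- pmin(df$EAF, 1 - df$EAF)
  rare <- !is.na(maf) & maf < maf_min
  drops <- c(palindromic = sum(pal), low_maf = sum(rare & !pal))
  keep <- df[!(pal | rare), , drop = FALSE]
  if (nrow(keep) == 0L)
    stop("munge removed every record (",
         paste(sprintf("%s=%d", names(drops), drops), collapse = ", "), ")")
  keep$chi2_capped <- (keep$BETA / keep$SE)^2 > chi2_cap
  new("GwasSumstats", variants = keep, meta = x@meta,
      dropCounts = as.integer(drops) |> setNames(names(drops)))
}

#' Read a square LD matrix
#'
#' Whitespace-delimited square matrix of r-squared (or correlation) values
#' with SNP IDs as both header row and first column.
#'
#' @param path File path.
#' @return Numeric matrix with SNP-ID dimnames.
#' @export
readLDMatrix <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- ids
  if (!identical(ids, colnames(m)))
    stop("LD matrix row and column SNP IDs differ")
  m
}

#' Write a square LD matrix
#' @param m Square matrix with SNP-ID dimnames.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeLDMatrix <- function(m, path) {
  df <- data.frame(SNP = rownames(m), m, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read per-SNP LD scores
#'
#' Tab-delimited two-column file (\code{snp_id}, \code{ldscore}).
#'
#' @param path File path.
#' @return Named numeric vector of LD scores.
#' @export
readLDScores <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  setNames(as.numeric(dt[[2]]), as.character(dt[[1]]))
}
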