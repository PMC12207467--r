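# File formats: LDSC-style whitespace-delimited summary statistics
# (header SNP A1 A2 N Z) and LD score tables (SNP, L2), gzip autodetected;
# canonical outputs are TSVs with a '#'-prefixed provenance header.

open_maybe_gz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  magic <- readBin(path, "raw", n = 2)
  if (length(magic) == 2 && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b))
    gzfile(path) else file(path)
}

#' Read an LDSC-style summary statistics file
#'
#' Whitespace- or tab-delimited with a header containing (case-insensitive)
#' `SNP A1 A2 N Z`; extra columns are ignored; gzip is autodetected from
#' the file's magic bytes. Rows with unparseable or missing values are
#' dropped with a warning; more than 1% such rows is an error, as is any
#' duplicated SNP identifier.
#'
#' @param path Path to the file.
#' @return Data frame with columns `snp, a1, a2, n, z`.
#' @export
read_sumstats <- function(path) {
  con <- open_maybe_gz(path)
  lines <- readLines(con)
  close(con)
  raw <- read.table(text = lines, header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "#")
  names(raw) <- tolower(names(raw))
  need <- c("snp", "a1", "a2", "n", "z")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing column(s) in ", path, ": ",
         paste(toupper(miss), collapse = ", "))
  out <- data.frame(snp = as.character(raw$snp),
                    a1 = as.character(raw$a1), a2 = as.character(raw$a2),
                    n = suppressWarnings(as.numeric(raw$n)),
                    z = suppressWarnings(as.numeric(raw$z)),
                    stringsAsFactors = FALSE)
  bad <- !complete.cases(out[c("n", "z")])
  if (any(bad)) {
    if (mean(bad) > 0.01)
      stop(sum(bad), " unparseable rows (> 1%) in ", path)
    warning("dropped ", sum(bad), " unparseable row(s) from ", path)
    out <- out[!bad, ]
  }
  if (anyDuplicated(out$snp))
    stop("duplicated SNP id in ", path, ": ",
         out$snp[duplicated(out$snp)][1])
  out
}

#' Write summary statistics in the LDSC dialect
#'
#' @param x Data frame with columns `snp, a1, a2, n, z` (case-insensitive).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  names(x) <- tolower(names(x))
  out <- x[c("snp", "a1", "a2", "n", "z")]
  names(out) <- c("SNP", "A1", "A2", "N", "Z")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con), add = TRUE)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an LD score table
#'
#' Accepts the `.l2.ldscore` dialect: a header containing (case-insensitive)
#' `SNP` and `L2`; other columns (CHR, BP, CM, MAF, ...) are ignored.
#'
#' @param path Path to the file (gzip autodetected).
#' @return Data frame with columns `snp, l2`.
#' @export
read_ldscores <- function(path) {
  con <- open_maybe_gz(path)
  lines <- readLines(con)
  close(con)
  if (length(lines) < 2) stop("empty LD score file: ", path)
  raw <- read.table(text = lines, header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "#")
  names(raw) <- tolower(names(raw))
  if (!all(c("snp", "l2") %in% names(raw)))
    stop("missing SNP/L2 column(s) in ", path)
  out <- data.frame(snp = as.character(raw$snp),
                    l2 = as.numeric(raw$l2), stringsAsFactors = FALSE)
  if (nrow(out) == 0) stop("empty LD score file: ", path)
  if (anyDuplicated(out$snp))
    stop("duplicated SNP id in ", path, ": ",
         out$snp[duplicated(out$snp)][1])
  out
}

#' @rdname read_ldscores
#' @param x Data frame with columns `snp, l2`.
#' @export
write_ldscores <- function(x, path) {
  names(x) <- tolower(names(x))
  out <- x[c("snp", "l2")]
  names(out) <- c("SNP", "L2")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con), add = TRUE)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write result tables with a provenance header
#'
#' Each named data frame in `tables` is written to
#' `<prefix>.<name>.tsv` with fixed column order, a fixed float format,
#' and '#'-prefixed header lines recording the package version, the
#' creation time, and any provenance fields supplied — so identical runs
#' produce byte-identical tables apart from the timestamp line, which can
#' be disabled.
#'
#' @param tables Named list of data frames.
#' @param prefix Output path prefix.
#' @param provenance Named character vector of extra header fields
#'   (e.g. seed, config hash).
#' @param timestamp Include a timestamp line? Default `FALSE` to keep
#'   outputs diffable.
#' @param digits Significant digits for numeric columns (default 10).
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(tables, prefix, provenance = character(0),
                          timestamp = FALSE, digits = 10) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  paths <- character(0)
  for (nm in names(tables)) {
    path <- paste0(prefix, ".", nm, ".tsv")
    hdr <- c(paste0("# partbias ", as.character(packageVersion("partbias"))),
             if (timestamp) paste0("# created ", format(Sys.time())),
             if (length(provenance))
               paste0("# ", names(provenance), " = ", provenance))
    tab <- tables[[nm]]
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], function(v) signif(v, digits))
    con <- file(path, "w")
    writeLines(hdr, con)
    suppressWarnings(write.table(tab, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE, append = TRUE))
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}
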