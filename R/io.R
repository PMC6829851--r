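# Standard-format input/output: genotype TSV, PLINK 1 binary, visit records.

#' Read and write genotype matrices as TSV
#'
#' TSV dialect: tab-separated, UTF-8, header row of SNP ids preceded by an
#' `id` column, one row per individual, allele counts in \{0, 1, 2\} with
#' missing written as `NA`. Write-then-read round-trips exactly.
#'
#' @param path file path.
#' @return `read_genotypes_tsv()`: integer matrix with individual ids as row
#'   names and SNP ids as column names.
#' @export
read_genotypes_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1] != "id") stop("genotype TSV must start with an 'id' column")
  G <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(G) <- "integer"
  rownames(G) <- as.character(d$id)
  if (any(G < 0L | G > 2L, na.rm = TRUE))
    stop("allele counts must be 0, 1, 2 or NA")
  G
}

#' @rdname read_genotypes_tsv
#' @param G genotype matrix (individuals x SNPs).
#' @export
write_genotypes_tsv <- function(G, path) {
  d <- data.frame(id = rownames(G) %||% as.character(seq_len(nrow(G))),
                  G, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

# PLINK 1 .bed 2-bit codes (SNP-major): 00 = hom A1 (2 minor alleles),
# 10 = het, 11 = hom A2 (0), 01 = missing.
plink_decode <- c(2L, NA_integer_, 1L, 0L)  # indexed by code + 1

#' Read a PLINK 1 binary fileset
#'
#' Reads `.bed`/`.bim`/`.fam` (SNP-major bit-packed `.bed` per the PLINK 1
#' specification). Allele counts are counts of the A1 allele (conventionally
#' the minor allele): homozygous A1 = 2, heterozygous = 1, homozygous
#' A2 = 0, missing = `NA`.
#'
#' @param prefix path without extension (reads `prefix.bed` etc.).
#' @return list with `genotypes` (matrix, individual ids from the `.fam`
#'   IID column, SNP ids from the `.bim`), `bim` and `fam` data frames.
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos",
                                         "a1", "a2"))
  fam <- utils::read.table(paste0(prefix, ".fam"), stringsAsFactors = FALSE,
                           col.names = c("fid", "iid", "pat", "mat", "sex",
                                         "pheno"))
  n <- nrow(fam); m <- nrow(bim)
  bed_path <- paste0(prefix, ".bed")
  raw <- readBin(bed_path, "raw", n = file.info(bed_path)$size)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (magic bytes mismatch)")
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported")
  bpv <- ceiling(n / 4)  # bytes per variant
  if (length(raw) != 3 + m * bpv)
    stop(".bed size disagrees with .bim/.fam dimensions")
  body <- as.integer(raw[-(1:3)])
  # expand each byte into its four 2-bit fields (little-endian within byte)
  codes <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, body %/% 64L)
  dim(codes) <- c(4L * bpv, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  G <- matrix(plink_decode[codes + 1L], n, m)
  dimnames(G) <- list(fam$iid, bim$snp_id)
  list(genotypes = G, bim = bim, fam = fam)
}

#' Write a genotype matrix as a PLINK 1 binary fileset
#'
#' Writes SNP-major `.bed` plus minimal `.bim`/`.fam`. A1 is the counted
#' allele. Round-trips through [read_plink] exactly, including missing
#' genotypes.
#'
#' @param G genotype matrix in \{0, 1, 2, NA\}.
#' @param prefix output path without extension.
#' @param bim optional data frame (chrom, snp_id, cm, pos, a1, a2).
#' @param fam optional data frame (fid, iid, pat, mat, sex, pheno).
#' @export
write_plink <- function(G, prefix, bim = NULL, fam = NULL) {
  n <- nrow(G); m <- ncol(G)
  if (is.null(bim))
    bim <- data.frame(chrom = 1L, snp_id = colnames(G) %||%
                        paste0("snp", seq_len(m)),
                      cm = 0L, pos = seq_len(m), a1 = "A", a2 = "B")
  if (is.null(fam))
    fam <- data.frame(fid = rownames(G) %||% paste0("ind", seq_len(n)),
                      iid = rownames(G) %||% paste0("ind", seq_len(n)),
                      pat = 0L, mat = 0L, sex = 0L, pheno = -9L)
  enc <- c(`0` = 3L, `1` = 2L, `2` = 0L)  # count -> 2-bit code; NA -> 01
  bpv <- ceiling(n / 4)
  pad <- 4L * bpv - n
  gcodes <- matrix(1L, n, m)  # default: missing (01)
  obs <- !is.na(G)
  gcodes[obs] <- enc[as.character(G[obs])]
  codes <- rbind(gcodes, matrix(0L, pad, m))  # pad bits ignored on read
  bytes <- codes[c(TRUE, FALSE, FALSE, FALSE), , drop = FALSE] +
    4L * codes[c(FALSE, TRUE, FALSE, FALSE), , drop = FALSE] +
    16L * codes[c(FALSE, FALSE, TRUE, FALSE), , drop = FALSE] +
    64L * codes[c(FALSE, FALSE, FALSE, TRUE), , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read genotypes in either supported format
#'
#' @param path TSV path, or PLINK prefix when `format = "plink"`.
#' @param format `"tsv"` or `"plink"`.
#' @return genotype matrix.
#' @export
read_genotypes <- function(path, format = c("tsv", "plink")) {
  format <- match.arg(format)
  if (format == "tsv") read_genotypes_tsv(path)
  else read_plink(path)$genotypes
}

#' Read a covariate TSV
#'
#' Tab-separated with a header; first column `id`, remaining columns numeric
#' covariates (sex, ancestry principal components, ...).
#'
#' @param path file path.
#' @return numeric matrix with individual ids as row names.
#' @export
read_covariates <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (names(d)[1] != "id") stop("covariate TSV must start with an 'id' column")
  M <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- as.character(d$id)
  M
}

#' Derive a survival phenotype from raw visit records
#'
#' Implements the two-distinct-dates phenotyping rule used with
#' billing-code-derived (phecode) diagnoses: an individual is a case when
#' the target code appears on at least two distinct dates - the event age is
#' the age on the second distinct code date - and a control when the code
#' never appears, censored at the age of the last visit. Individuals with
#' the code on exactly one date fit neither definition and are excluded.
#' Entry age (left truncation) is the age at the first visit of any kind.
#'
#' Ages come from a `birthdate` column (dates converted at 365.25 days per
#' year) or, failing that, an `age` column giving age at each visit.
#' Individuals whose event age does not exceed their entry age (e.g. the
#' code on the first-ever visit date) cannot contribute a valid
#' (entry, exit] interval and are excluded with a logged reason.
#'
#' @param visits data frame with columns `id`, `date` (parseable as Date),
#'   `code` (diagnosis code or `NA`/empty for code-free visits), and
#'   `birthdate` or `age`.
#' @param target_code the diagnosis code defining the phenotype.
#' @return list with `pheno` (a [survival_phenotype]), `labels` (named
#'   character: "case"/"control"), and `exclusions` (id, reason).
#' @export
build_survival_phenotype <- function(visits, target_code) {
  need_age <- !("birthdate" %in% names(visits)) && !("age" %in% names(visits))
  if (!all(c("id", "date", "code") %in% names(visits)) || need_age)
    stop("visits need columns id, date, code and birthdate or age")
  visits$date <- as.Date(visits$date)
  if (anyNA(visits$date)) stop("unparseable visit dates")
  if ("birthdate" %in% names(visits)) {
    bd <- as.Date(visits$birthdate)
    visits$age <- as.numeric(visits$date - bd) / 365.25
  }
  if (any(visits$age < 0)) stop("negative age at visit")
  ids <- unique(visits$id)
  entry <- exit <- numeric(0); status <- integer(0)
  kept_ids <- character(0); labels <- character(0)
  excl <- list()
  for (ind in ids) {
    v <- visits[visits$id == ind, , drop = FALSE]
    v <- v[order(v$date), , drop = FALSE]
    hit <- !is.na(v$code) & v$code == target_code
    code_dates <- sort(unique(v$date[hit]))
    e_age <- min(v$age)
    if (length(code_dates) == 1L) {
      excl[[length(excl) + 1L]] <- data.frame(id = ind, reason = "single_code_date")
      next
    }
    if (length(code_dates) >= 2L) {
      x_age <- min(v$age[v$date == code_dates[2L]])
      st <- 1L; lab <- "case"
    } else {
      x_age <- max(v$age)
      st <- 0L; lab <- "control"
    }
    if (x_age <= e_age) {
      excl[[length(excl) + 1L]] <- data.frame(id = ind, reason = "exit_not_after_entry")
      next
    }
    kept_ids <- c(kept_ids, as.character(ind))
    labels <- c(labels, lab)
    entry <- c(entry, e_age); exit <- c(exit, x_age); status <- c(status, st)
  }
  if (!length(kept_ids)) stop("no individuals usable for the phenotype")
  list(pheno = survival_phenotype(entry, exit, status, id = kept_ids),
       labels = stats::setNames(labels, kept_ids),
       exclusions = if (length(excl)) do.call(rbind, excl) else
         data.frame(id = character(0), reason = character(0)))
}

#' Read an LD-block map TSV
#'
#' Columns `phenotype`, `block_id`, `snp_id`: one row per SNP on the scanned
#' platform belonging to a known phenotype-LD-block association.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_block_map <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("phenotype", "block_id", "snp_id")
  if (!all(need %in% names(d)))
    stop("block map TSV needs columns: ", paste(need, collapse = ", "))
  d
}
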