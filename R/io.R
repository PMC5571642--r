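# File formats: PLINK .bed/.bim/.fam (v1.00 SNP-major), plain dosage TSV,
# GCTA binary GRM triplet, phenotype/covariate tables keyed by FID/IID.

# 2-bit PLINK codes, SNP-major. The counted (dosage) allele is .bim A1:
#   00 -> two copies of A1 (dosage 2), 10 -> het (1), 11 -> no A1 (0),
#   01 -> missing.
.plink_code_of_dosage <- c(`0` = 3L, `1` = 2L, `2` = 0L)   # NA -> 1L
.plink_dosage_of_code <- c(2L, NA_integer_, 1L, 0L)        # index = code + 1

#' Write genotypes to a PLINK binary fileset
#'
#' Writes `prefix`.bed (v1.00 magic bytes, SNP-major), `prefix`.bim and
#' `prefix`.fam. Chromosome and position are synthesized (chromosome 1,
#' positions 1..S); alleles are labeled A/B with B the counted (reference)
#' allele, so A1 = B. Family and parent identifiers come from the pedigree
#' when present, making simulated relatedness visible to external tools.
#'
#' @param genotypes A `genotype_data`.
#' @param prefix Output path prefix.
#' @return Invisibly, the prefix.
#' @export
write_plink <- function(genotypes, prefix) {
  stopifnot(inherits(genotypes, "genotype_data"))
  G <- genotypes$dosages
  N <- nrow(G)
  S <- ncol(G)
  ped <- genotypes$pedigree
  fam <- data.frame(
    fid = if (!is.null(ped)) ped$fid else genotypes$subject_ids,
    iid = genotypes$subject_ids,
    pat = if (!is.null(ped)) ped$pat else "0",
    mat = if (!is.null(ped)) ped$mat else "0",
    sex = 0L, pheno = -9L, stringsAsFactors = FALSE)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chr = 1L, id = genotypes$snp_ids, cm = 0L,
                    pos = seq_len(S), a1 = "B", a2 = "A",
                    stringsAsFactors = FALSE)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  codes <- matrix(1L, N, S)                      # default: missing
  obs <- !is.na(G)
  codes[obs] <- .plink_code_of_dosage[as.character(G[obs])]
  nb <- ceiling(N / 4)
  pad <- matrix(0L, nb * 4L - N, S)              # pad bits are zero
  codes <- rbind(codes, pad)
  dim(codes) <- c(4L, nb * S)
  bytes <- as.integer(c(1L, 4L, 16L, 64L) %*% codes)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}

#' Read genotypes from a PLINK binary fileset
#'
#' Reads `prefix`.bed/.bim/.fam. Only the v1.00 SNP-major layout is
#' supported; the magic bytes and the payload size are checked against the
#' .fam/.bim dimensions. Dosages count the .bim A1 allele; missing genotypes
#' become `NA` (mean-imputed later by [compute_grm()]).
#'
#' @param prefix Path prefix of the fileset.
#' @param autosomes_only Drop SNPs whose .bim chromosome code is not 1..22.
#' @return A `genotype_data` with a pedigree built from the .fam file.
#' @export
read_plink <- function(prefix, autosomes_only = FALSE) {
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           colClasses = "character")
  names(fam) <- c("fid", "iid", "pat", "mat", "sex", "pheno")[seq_len(ncol(fam))]
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           colClasses = "character")
  names(bim) <- c("chr", "id", "cm", "pos", "a1", "a2")[seq_len(ncol(bim))]
  N <- nrow(fam)
  S <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), what = "raw",
                 n = file.info(paste0(prefix, ".bed"))$size)
  if (length(raw) < 3 || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b))
    stop("not a PLINK .bed file: magic-number mismatch")
  if (raw[3L] != as.raw(0x01))
    stop("only SNP-major (v1.00) .bed files are supported")
  nb <- ceiling(N / 4)
  if (length(raw) - 3L != nb * S)
    stop("dimension mismatch: .bed payload has ", length(raw) - 3L,
         " bytes but .fam/.bim imply ", nb * S)
  b <- as.integer(raw[-(1:3)])
  codes <- rbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L, (b %/% 64L) %% 4L)
  dim(codes) <- c(4L * nb, S)
  codes <- codes[seq_len(N), , drop = FALSE]
  dos <- matrix(.plink_dosage_of_code[codes + 1L], N, S)
  ped <- data.frame(fid = fam$fid, iid = fam$iid, pat = fam$pat, mat = fam$mat,
                    role = ifelse(fam$pat == "0" & fam$mat == "0",
                                  "founder", "child"),
                    origin = NA_character_, stringsAsFactors = FALSE)
  out <- genotype_data(dos, subject_ids = fam$iid, snp_ids = bim$id,
                       pedigree = ped)
  attr(out, "bim") <- bim
  if (autosomes_only) {
    keep <- suppressWarnings(as.integer(bim$chr)) %in% 1:22
    out$dosages <- out$dosages[, keep, drop = FALSE]
    out$snp_ids <- out$snp_ids[keep]
    attr(out, "bim") <- bim[keep, , drop = FALSE]
  }
  out
}

#' Write a dosage matrix as TSV
#'
#' Subjects in rows (first columns FID, IID), SNPs in columns; entries 0/1/2
#' or NA.
#'
#' @param genotypes A `genotype_data`.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_data"))
  ped <- genotypes$pedigree
  df <- data.frame(FID = if (!is.null(ped)) ped$fid else genotypes$subject_ids,
                   IID = genotypes$subject_ids,
                   genotypes$dosages, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dosage matrix from TSV
#'
#' Expects the layout of [write_dosage_tsv()]. Any cell that is not 0, 1, 2
#' or NA raises an error naming the offending row and column.
#'
#' @param path Input file.
#' @return A `genotype_data`.
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("FID", "IID") %in% names(df)))
    stop("dosage TSV must have FID and IID columns")
  iid <- as.character(df$IID)
  fid <- as.character(df$FID)
  M <- as.matrix(df[, setdiff(names(df), c("FID", "IID")), drop = FALSE])
  bad <- which(!(M %in% c(0, 1, 2) | is.na(M)))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(M))
    stop("invalid dosage '", M[bad[1L]], "' at row ", rc[1L],
         " (subject ", iid[rc[1L]], "), column ", colnames(M)[rc[2L]])
  }
  storage.mode(M) <- "integer"
  ped <- data.frame(fid = fid, iid = iid, pat = "0", mat = "0",
                    role = "founder", origin = NA_character_,
                    stringsAsFactors = FALSE)
  genotype_data(M, subject_ids = iid, snp_ids = colnames(M), pedigree = ped)
}

#' Write a GRM in GCTA binary format
#'
#' Writes `prefix`.grm.bin (lower triangle including the diagonal,
#' little-endian 4-byte floats), `prefix`.grm.N.bin (SNP counts, same layout)
#' and `prefix`.grm.id (FID/IID TSV).
#'
#' @param grm A `grm` object.
#' @param prefix Output prefix.
#' @return Invisibly, the prefix.
#' @export
write_gcta_grm <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  N <- nrow(grm$K)
  lower <- grm$K[upper.tri(grm$K, diag = TRUE)]       # column-major upper
  # GCTA stores row-major lower triangle == column-major upper triangle
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lower), con, size = 4L, endian = "little")
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(grm$n_snps_used), length(lower)), con, size = 4L,
           endian = "little")
  close(con)
  utils::write.table(data.frame(grm$subject_ids, grm$subject_ids),
                     paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a GRM from GCTA binary format
#'
#' @param prefix Prefix of the `.grm.bin`/`.grm.N.bin`/`.grm.id` triplet.
#' @return A `grm` object.
#' @export
read_gcta_grm <- function(prefix) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"), header = FALSE,
                           colClasses = "character")
  N <- nrow(ids)
  m <- N * (N + 1) / 2
  vals <- readBin(paste0(prefix, ".grm.bin"), what = "numeric", n = m + 1L,
                  size = 4L, endian = "little")
  if (length(vals) != m)
    stop("dimension mismatch: .grm.bin holds ", length(vals),
         " values but .grm.id implies ", m)
  K <- matrix(0, N, N)
  K[upper.tri(K, diag = TRUE)] <- vals
  K <- K + t(K) - diag(diag(K))
  nfile <- paste0(prefix, ".grm.N.bin")
  n_snps <- if (file.exists(nfile))
    as.integer(round(readBin(nfile, "numeric", n = 1L, size = 4L,
                             endian = "little")))
  else NA_integer_
  structure(list(K = K, n_snps_used = n_snps, subject_ids = ids[[2L]]),
            class = "grm")
}

#' Write phenotypes as TSV
#'
#' Columns FID, IID, then one column per trait, with a header row.
#'
#' @param phenotypes A `phenotype_data`.
#' @param path Output file.
#' @param fid Optional family identifiers (defaults to the subject ids).
#' @return Invisibly, the path.
#' @export
write_phenotypes <- function(phenotypes, path, fid = NULL) {
  stopifnot(inherits(phenotypes, "phenotype_data"))
  df <- data.frame(FID = fid %||% phenotypes$subject_ids,
                   IID = phenotypes$subject_ids,
                   phenotypes$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read phenotypes from TSV
#'
#' @param path File with columns FID, IID and one numeric column per trait.
#' @return A `phenotype_data`; the FID column is kept as attribute `fid`.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("FID", "IID") %in% names(df)))
    stop("phenotype TSV must have FID and IID columns")
  traits <- setdiff(names(df), c("FID", "IID"))
  M <- as.matrix(df[, traits, drop = FALSE])
  storage.mode(M) <- "double"
  out <- phenotype_data(M, subject_ids = as.character(df$IID),
                        trait_names = traits)
  attr(out, "fid") <- as.character(df$FID)
  out
}

#' Read a covariate table from TSV
#'
#' Columns FID, IID, then covariates. Character columns are one-hot encoded
#' (first level dropped); numeric columns pass through.
#'
#' @param path Input file.
#' @return Numeric matrix with subject ids as row names.
#' @export
read_covariates <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("FID", "IID") %in% names(df)))
    stop("covariate TSV must have FID and IID columns")
  iid <- as.character(df$IID)
  covs <- df[, setdiff(names(df), c("FID", "IID")), drop = FALSE]
  pieces <- lapply(names(covs), function(nm) {
    v <- covs[[nm]]
    if (is.numeric(v)) {
      out <- matrix(v, ncol = 1L, dimnames = list(NULL, nm))
    } else {
      f <- factor(v)
      out <- stats::model.matrix(~f)[, -1L, drop = FALSE]
      colnames(out) <- paste0(nm, levels(f)[-1L])
    }
    out
  })
  M <- do.call(cbind, pieces)
  rownames(M) <- iid
  M
}
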