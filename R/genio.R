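#' Write pedigree and genotypes as PLINK text PED/MAP
#'
#' PED columns: family id, individual id, father, mother, sex, phenotype
#' placeholder (`-9`), then two allele columns per SNP; a missing allele is
#' written `"0"`. MAP columns: chromosome, SNP id, genetic distance (0),
#' 1-based bp position.
#'
#' @param ped pedigree data.frame (`fid`, `iid`, `pat`, `mat`, `sex`).
#' @param geno genotype matrix of minor-allele counts (individual x SNP).
#' @param manifest manifest supplying `chrom`, `pos`, `minor_allele`,
#'   `major_allele` per SNP.
#' @param ped_path,map_path output paths.
#' @return invisibly, the two paths.
#' @export
write_pedmap <- function(ped, geno, manifest, ped_path, map_path) {
  man <- manifest[match(colnames(geno), manifest$snp), , drop = FALSE]
  if (anyNA(man$snp))
    stop("manifest does not cover every genotype column")
  utils::write.table(
    data.frame(man$chrom, man$snp, 0L, man$pos),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  G <- geno[ped$iid, , drop = FALSE]
  n <- nrow(G); L <- ncol(G)
  a1 <- matrix(rep(man$minor_allele, each = n), n, L)
  a2 <- matrix(rep(man$major_allele, each = n), n, L)
  A1 <- ifelse(is.na(G), "0", ifelse(G >= 1L, a1, a2))
  A2 <- ifelse(is.na(G), "0", ifelse(G == 2L, a1, a2))
  allele_cols <- matrix("", n, 2L * L)
  allele_cols[, seq(1L, 2L * L, by = 2L)] <- A1
  allele_cols[, seq(2L, 2L * L, by = 2L)] <- A2
  lines <- do.call(paste, c(list(ped$fid, ped$iid, ped$pat, ped$mat, ped$sex,
                                 -9L),
                            split(allele_cols, col(allele_cols))))
  writeLines(lines, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read PLINK text PED/MAP into pedigree and additive genotypes
#'
#' Alleles are recoded to minor-allele counts; the minor allele at each SNP
#' is the rarer allele among founders (ties broken lexicographically), so
#' offspring transmissions cannot bias the coding. `"0 0"` becomes missing.
#' Offspring genotypes that are Mendelian-impossible given both parents are
#' set to missing, counted, and reported in a message.
#'
#' @param ped_path,map_path input files.
#' @return a list: `ped` (pedigree data.frame), `geno` (integer matrix of
#'   minor-allele counts), `snps` (MAP data.frame plus the inferred
#'   minor/major alleles), `n_mendel_errors`.
#' @export
read_pedmap <- function(ped_path, map_path) {
  snps <- utils::read.table(map_path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE,
                            col.names = c("chrom", "snp", "cm", "pos"))
  L <- nrow(snps)
  raw <- readLines(ped_path)
  toks <- strsplit(trimws(raw), "[ \t]+")
  nbad <- which(lengths(toks) != 6L + 2L * L)
  if (length(nbad))
    stop("malformed PED line(s): ", paste(utils::head(nbad, 5L), collapse = ", "),
         " (expected ", 6L + 2L * L, " fields)")
  M <- matrix(unlist(toks), nrow = length(toks), byrow = TRUE)
  ped <- data.frame(fid = M[, 1L], iid = M[, 2L], pat = M[, 3L], mat = M[, 4L],
                    sex = as.integer(M[, 5L]), stringsAsFactors = FALSE)
  if (anyDuplicated(ped$iid))
    stop("duplicate individual ids in PED file")
  A1 <- M[, 6L + seq(1L, 2L * L, by = 2L), drop = FALSE]
  A2 <- M[, 6L + seq(2L, 2L * L, by = 2L), drop = FALSE]
  A1[A1 == "0"] <- NA
  A2[A2 == "0"] <- NA

  founder <- ped$pat == "0" & ped$mat == "0"
  minor <- major <- character(L)
  G <- matrix(NA_integer_, nrow(ped), L, dimnames = list(ped$iid, snps$snp))
  for (j in seq_len(L)) {
    als <- c(A1[founder, j], A2[founder, j])
    tab <- sort(table(als))
    if (length(tab) == 0L) {        # no founder calls: fall back to everyone
      tab <- sort(table(c(A1[, j], A2[, j])))
    }
    if (length(tab) == 1L) {
      minor[j] <- names(tab)[1L]
      major[j] <- names(tab)[1L]
    } else {
      # rarer allele is minor; exact ties broken lexicographically
      if (tab[[1L]] == tab[[2L]]) {
        nm <- sort(names(tab)[1:2])
        minor[j] <- nm[1L]; major[j] <- nm[2L]
      } else {
        minor[j] <- names(tab)[1L]; major[j] <- names(tab)[2L]
      }
    }
    G[, j] <- (A1[, j] == minor[j]) + (A2[, j] == minor[j])
  }

  # Mendelian screen: child's count must be reachable from both parents
  fi <- match(ped$pat, ped$iid)
  mi <- match(ped$mat, ped$iid)
  kids <- which(!is.na(fi) & !is.na(mi))
  n_err <- 0L
  if (length(kids)) {
    Gf <- G[fi[kids], , drop = FALSE]
    Gm <- G[mi[kids], , drop = FALSE]
    Gk <- G[kids, , drop = FALSE]
    lo <- (Gf == 2L) + (Gm == 2L)
    hi <- (Gf >= 1L) + (Gm >= 1L)
    bad <- !is.na(Gk) & !is.na(lo) & !is.na(hi) & (Gk < lo | Gk > hi)
    n_err <- sum(bad)
    if (n_err > 0L) {
      Gk[bad] <- NA_integer_
      G[kids, ] <- Gk
      message(n_err, " Mendelian inconsistency(ies) set to missing")
    }
  }
  snps$minor_allele <- minor
  snps$major_allele <- major
  list(ped = ped, geno = G, snps = snps, n_mendel_errors = n_err)
}

#' Write / read a phenotype-covariate table
#'
#' Plain tab-separated text with a header row; missing values are written as
#' `NA`.
#'
#' @param pheno phenotype data.frame.
#' @param path file path.
#' @return `read_phenotypes()` returns the data.frame; `write_phenotypes()`
#'   returns the path invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA")
}

#' Decompose a pedigree into nuclear families
#'
#' Every distinct (father, mother) couple with at least one offspring forms
#' one nuclear unit, so each parent-offspring triple is covered exactly once.
#' Validates that named parents exist in the same family and that nobody is
#' their own ancestor.
#'
#' @param ped pedigree data.frame (`fid`, `iid`, `pat`, `mat`).
#' @return a list of nuclear units, each a list with `fid`, `father`,
#'   `mother`, `offspring` (character vector of iids).
#' @export
nuclear_families <- function(ped) {
  ped_depths(ped)   # validates: complete parents, no cycles
  kids <- which(ped$pat != "0" & ped$mat != "0")
  missing_parent <- kids[!(ped$pat[kids] %in% ped$iid) |
                           !(ped$mat[kids] %in% ped$iid)]
  if (length(missing_parent))
    stop("parent(s) not present in pedigree for: ",
         paste(utils::head(ped$iid[missing_parent], 5L), collapse = ", "))
  fam_of <- stats::setNames(ped$fid, ped$iid)
  cross <- kids[fam_of[ped$pat[kids]] != ped$fid[kids] |
                  fam_of[ped$mat[kids]] != ped$fid[kids]]
  if (length(cross))
    stop("parents recorded in a different family for: ",
         paste(utils::head(ped$iid[cross], 5L), collapse = ", "))
  key <- paste(ped$fid[kids], ped$pat[kids], ped$mat[kids], sep = "\r")
  split_k <- split(ped$iid[kids], key)
  lapply(names(split_k), function(k) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    list(fid = parts[1L], father = parts[2L], mother = parts[3L],
         offspring = split_k[[k]])
  })
}

#' Apply the missing-data exclusion filter
#'
#' Rows with missing smoking status are removed first, then rows missing any
#' other required covariate; the log reports the count per reason and the
#' final sample size. Mirrors the common practice of excluding members with
#' unknown smoking status or covariates before family-based testing.
#'
#' @param pheno phenotype data.frame.
#' @param required character vector of required column names; `"smoking"`
#'   (when present in `required`) is counted as its own exclusion reason.
#' @return a list of class `exclusion_log`: `pheno` (retained rows),
#'   `log` (data.frame of reason/count), `n_initial`, `n_final`.
#' @export
apply_exclusions <- function(pheno, required = c("smoking", "alcohol")) {
  missing_cols <- setdiff(required, names(pheno))
  if (length(missing_cols))
    stop("required field(s) absent from table: ",
         paste(missing_cols, collapse = ", "))
  n0 <- nrow(pheno)
  reasons <- character(0)
  counts <- integer(0)
  keep <- rep(TRUE, n0)
  if ("smoking" %in% required) {
    drop_s <- is.na(pheno$smoking)
    reasons <- c(reasons, "missing smoking status")
    counts <- c(counts, sum(drop_s))
    keep <- keep & !drop_s
  }
  other <- setdiff(required, "smoking")
  if (length(other)) {
    miss_any <- Reduce(`|`, lapply(other, function(cl) is.na(pheno[[cl]])))
    drop_c <- keep & miss_any
    reasons <- c(reasons, "missing covariate(s)")
    counts <- c(counts, sum(drop_c))
    keep <- keep & !drop_c
  }
  out <- pheno[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("exclusion filter removed every row", call. = FALSE)
  structure(list(pheno = out,
                 log = data.frame(reason = reasons, n_excluded = counts),
                 n_initial = n0, n_final = nrow(out)),
            class = "exclusion_log")
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat("Exclusion filter:", x$n_initial, "rows in\n")
  for (i in seq_len(nrow(x$log)))
    cat(sprintf("  - %-28s %d\n", x$log$reason[i], x$log$n_excluded[i]))
  cat("  retained:", x$n_final, "\n")
  invisible(x)
}
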