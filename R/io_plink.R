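# PLINK 1.9 binary/text genotype formats. Dog chromosome dialect: autosomes
# 1-38; internally X=39, Y=40, MT=41, written as PLINK dog codes X=39, Y=40,
# MT=42 and mapped back on read.

plink_chrom_out <- function(chrom) {
  ch <- as.character(chrom)
  ch[ch == "X"] <- "39"; ch[ch == "Y"] <- "40"
  ch[ch %in% c("MT", "41")] <- "42"
  ch
}

plink_chrom_in <- function(chrom) {
  ch <- as.character(chrom)
  ch[ch == "X"] <- "39"; ch[ch == "Y"] <- "40"
  ch[ch %in% c("MT", "42")] <- "41"
  as.integer(ch)
}

#' Write genotypes in PLINK format
#'
#' `format = "bed"` writes the binary BED/BIM/FAM triplet (SNP-major, the
#' standard 3-byte magic `0x6c 0x1b 0x01`); `format = "ped"` writes text
#' PED/MAP. Genotypes are A1 (derived/minor) dosages; missing is `NA`.
#'
#' @param genotypes dosage matrix, individuals x SNPs (0/1/2/`NA`)
#' @param map data.frame with columns `chrom`, `id`, `pos` and optionally
#'   `a1`, `a2` (defaults `"A"`/`"C"`, A1 = derived allele)
#' @param fam data.frame with columns `fid`, `iid` and optionally `pat`,
#'   `mat`, `sex` (1 male/2 female/0 unknown), `phenotype` (1 control/2 case
#'   or quantitative; `-9` missing)
#' @param prefix output path prefix
#' @param format `"bed"` or `"ped"`
#' @param overwrite overwrite existing files? (default `FALSE`)
#' @return `prefix`, invisibly
#' @export
write_plink <- function(genotypes, map, fam, prefix, format = c("bed", "ped"),
                        overwrite = FALSE) {
  format <- match.arg(format)
  stopifnot(is.matrix(genotypes), nrow(genotypes) == nrow(fam),
            ncol(genotypes) == nrow(map))
  if (is.null(map$a1)) map$a1 <- rep("A", nrow(map))
  if (is.null(map$a2)) map$a2 <- rep("C", nrow(map))
  for (col in c("pat", "mat")) if (is.null(fam[[col]])) fam[[col]] <- rep(0L, nrow(fam))
  if (is.null(fam$sex)) fam$sex <- rep(0L, nrow(fam))
  if (is.null(fam$phenotype)) fam$phenotype <- rep(-9, nrow(fam))
  exts <- if (format == "bed") c(".bed", ".bim", ".fam") else c(".ped", ".map")
  files <- paste0(prefix, exts)
  if (!overwrite && any(file.exists(files)))
    stop("output files for prefix '", prefix,
         "' already exist (use overwrite = TRUE)")
  n <- nrow(genotypes); m <- ncol(genotypes)
  chrom_out <- plink_chrom_out(map$chrom)
  if (format == "bed") {
    write.table(data.frame(chrom_out, map$id, rep(0, nrow(map)), map$pos, map$a1, map$a2),
                files[2], quote = FALSE, sep = "\t",
                row.names = FALSE, col.names = FALSE)
    write.table(fam[, c("fid", "iid", "pat", "mat", "sex", "phenotype")],
                files[3], quote = FALSE, sep = " ",
                row.names = FALSE, col.names = FALSE)
    # 2-bit codes, LSB first: 00 hom A1, 01 missing, 10 het, 11 hom A2
    code <- matrix(3L, n, max(m, 1L))
    if (m > 0) {
      code[genotypes == 2] <- 0L
      code[genotypes == 1] <- 2L
      code[is.na(genotypes)] <- 1L
    }
    bpr <- ceiling(n / 4)
    con <- file(files[1], "wb")
    on.exit(close(con))
    writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
    if (m > 0) {
      idx <- seq_len(n)
      bytes <- matrix(0L, bpr, m)
      for (k in 0:3) {
        sel <- idx[(idx - 1) %% 4 == k]
        if (length(sel)) {
          rows <- ((sel - 1) %/% 4) + 1
          bytes[rows, ] <- bytes[rows, ] +
            code[sel, , drop = FALSE] * as.integer(4^k)
        }
      }
      writeBin(as.raw(bytes), con)
    }
  } else {
    write.table(data.frame(chrom_out, map$id, rep(0, nrow(map)), map$pos), files[2],
                quote = FALSE, sep = "\t", row.names = FALSE,
                col.names = FALSE)
    al <- function(g, a1, a2)
      ifelse(is.na(g), "0 0",
             ifelse(g == 2, paste(a1, a1),
                    ifelse(g == 1, paste(a1, a2), paste(a2, a2))))
    lines <- vapply(seq_len(n), function(i) {
      gt <- if (m > 0)
        paste(mapply(al, genotypes[i, ], map$a1, map$a2), collapse = " ")
      else ""
      trimws(paste(fam$fid[i], fam$iid[i], fam$pat[i], fam$mat[i], fam$sex[i],
                   fam$phenotype[i], gt))
    }, character(1))
    writeLines(lines, files[1])
  }
  invisible(prefix)
}

#' Read genotypes in PLINK format
#'
#' Reads a BED/BIM/FAM triplet (SNP-major BED) or a PED/MAP pair. Missing
#' genotypes are preserved as `NA`; positions are 1-based bp.
#'
#' @param prefix path prefix (file extensions are appended)
#' @return list with `genotypes` (individuals x SNPs A1-dosage matrix), `map`
#'   and `fam` data.frames
#' @export
read_plink <- function(prefix) {
  if (file.exists(paste0(prefix, ".bed"))) {
    bim <- read.table(paste0(prefix, ".bim"), header = FALSE,
                      col.names = c("chrom", "id", "cm", "pos", "a1", "a2"),
                      colClasses = c("character", "character", "numeric",
                                     "numeric", "character", "character"))
    fam <- read.table(paste0(prefix, ".fam"), header = FALSE,
                      col.names = c("fid", "iid", "pat", "mat", "sex",
                                    "phenotype"))
    n <- nrow(fam); m <- nrow(bim)
    raw <- readBin(paste0(prefix, ".bed"), "raw",
                   n = file.size(paste0(prefix, ".bed")))
    if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
      stop("not a PLINK BED file: bad magic bytes at offset 0-1")
    if (raw[3] != as.raw(0x01))
      stop("unsupported BED mode byte at offset 2 (expect SNP-major 0x01)")
    bpr <- ceiling(n / 4)
    body <- raw[-(1:3)]
    if (length(body) != bpr * m)
      stop("truncated BED record: expected ", bpr * m, " body bytes, found ",
           length(body))
    codes <- matrix(0L, n, m)
    if (m > 0 && n > 0) {
      b <- matrix(as.integer(body), bpr, m)
      for (k in 0:3) {
        sel <- which((seq_len(n) - 1) %% 4 == k)
        rows <- ((sel - 1) %/% 4) + 1
        codes[sel, ] <- (b[rows, , drop = FALSE] %/% as.integer(4^k)) %% 4L
      }
    }
    geno <- matrix(NA_integer_, n, m)
    geno[codes == 0L] <- 2L
    geno[codes == 2L] <- 1L
    geno[codes == 3L] <- 0L
    bim$chrom <- plink_chrom_in(bim$chrom)
    list(genotypes = geno, map = bim, fam = fam)
  } else if (file.exists(paste0(prefix, ".ped"))) {
    map <- read.table(paste0(prefix, ".map"), header = FALSE,
                      col.names = c("chrom", "id", "cm", "pos"),
                      colClasses = c("character", "character", "numeric",
                                     "numeric"))
    ped <- read.table(paste0(prefix, ".ped"), header = FALSE,
                      colClasses = "character")
    m <- nrow(map)
    if (ncol(ped) != 6 + 2 * m)
      stop("PED/MAP length disagreement: ", ncol(ped) - 6,
           " allele columns for ", m, " markers")
    fam <- data.frame(fid = ped[[1]], iid = ped[[2]],
                      pat = as.integer(ped[[3]]), mat = as.integer(ped[[4]]),
                      sex = as.integer(ped[[5]]),
                      phenotype = as.numeric(ped[[6]]))
    geno <- matrix(NA_integer_, nrow(ped), m)
    a1 <- a2 <- character(m)
    for (j in seq_len(m)) {
      x1 <- ped[[5 + 2 * j]]; x2 <- ped[[6 + 2 * j]]
      tab <- table(c(x1, x2))
      tab <- tab[names(tab) != "0"]
      als <- names(tab)[order(tab, names(tab))]  # A1 = minor, ties by name
      a1[j] <- if (length(als)) als[1] else "A"
      a2[j] <- if (length(als) > 1) als[length(als)] else "C"
      cnt <- (x1 == a1[j]) + (x2 == a1[j])
      cnt[x1 == "0" | x2 == "0"] <- NA
      geno[, j] <- as.integer(cnt)
    }
    map$a1 <- a1; map$a2 <- a2
    map$chrom <- plink_chrom_in(map$chrom)
    list(genotypes = geno, map = map[, c("chrom", "id", "cm", "pos", "a1",
                                         "a2")], fam = fam)
  } else {
    stop("no PLINK fileset found at prefix '", prefix, "'")
  }
}

#' Write a simulated marker panel as PLINK files
#'
#' BIM rows carry the chromosome, a synthetic marker id, 0 cM, the bp position
#' and alleles with the derived allele as A1; the FAM family id is the breed
#' population, and the phenotype column is 1/2-coded status when a
#' `phenotype_set` is supplied.
#'
#' @param panel a `haplotype_panel`
#' @param markers a `marker_panel` (`NULL` writes every segregating site)
#' @param prefix output prefix
#' @param phenotypes optional `phenotype_set` aligned with the panel
#' @param format,overwrite passed to [write_plink()]
#' @return `prefix`, invisibly
#' @export
write_panel_plink <- function(panel, markers = NULL, prefix,
                              phenotypes = NULL, format = "bed",
                              overwrite = FALSE) {
  sites <- if (is.null(markers)) seq_len(panel$n_site) else markers$sites
  geno <- panel_dosage(panel, sites = sites)
  map <- data.frame(chrom = panel$chrom[sites],
                    id = sprintf("snp%d_%d", panel$chrom[sites],
                                 panel$pos[sites]),
                    pos = panel$pos[sites], a1 = "A", a2 = "C")
  fam <- data.frame(fid = panel$ind_pop,
                    iid = sprintf("ind%05d", seq_len(n_individuals(panel))),
                    phenotype = if (is.null(phenotypes)) -9 else
                      phenotypes$status + 1L)
  write_plink(geno, map, fam, prefix, format = format, overwrite = overwrite)
  pops <- data.frame(individual_id = fam$iid, population_id = fam$fid)
  write.table(pops, paste0(prefix, ".pops.tsv"), quote = FALSE, sep = "\t",
              row.names = FALSE)
  invisible(prefix)
}
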