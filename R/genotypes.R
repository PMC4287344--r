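#' Describe variants to simulate
#'
#' Helper building the per-variant specification consumed by
#' [simulate_genotypes()]. Variants sharing a `block` label are placed on a
#' common founder haplotype pool and therefore show positive linkage
#' disequilibrium; variants in different blocks segregate independently
#' (free recombination between blocks).
#'
#' @param maf Target minor allele frequencies, in (0, 0.5].
#' @param block Block labels (recycled); defaults to one block per variant.
#' @param chr,pos Chromosome and position metadata; positions default to a
#'   regular grid within chromosome.
#' @param id Variant ids; default `"snp1"`, `"snp2"`, ...
#' @return A tibble with columns `id`, `chr`, `pos`, `maf`, `block`.
#' @export
variant_spec <- function(maf, block = NULL, chr = 1L, pos = NULL, id = NULL) {
  m <- length(maf)
  if (any(!is.finite(maf)) || any(maf <= 0) || any(maf > 0.5)) {
    abort("`maf` must lie in (0, 0.5].", class = "mqtl_invalid_argument")
  }
  tibble::tibble(
    id = id %||% sprintf("snp%d", seq_len(m)),
    chr = rep_len(as.integer(chr), m),
    pos = pos %||% (seq_len(m) * 1000L),
    maf = as.numeric(maf),
    block = rep_len(block %||% sprintf("b%d", seq_len(m)), m))
}

# Ladder haplotype pool for one LD block: variants ordered by descending MAF
# are nested, so each haplotype carries a prefix of the (sorted) variants.
# Haplotype frequencies are chosen so every variant hits its target MAF
# exactly in expectation; nesting induces strong positive within-block r2.
block_pool <- function(mafs) {
  ord <- order(mafs, decreasing = TRUE)
  L <- length(mafs)
  pool <- matrix(0L, L + 1L, L)
  for (i in seq_len(L)) pool[(i + 1L):(L + 1L), ord[i]] <- 1L
  m_sorted <- mafs[ord]
  freq <- c(1 - m_sorted[1],
            if (L > 1) m_sorted[-L] - m_sorted[-1] else numeric(0),
            m_sorted[L])
  if (any(freq < -1e-12)) abort("internal: bad haplotype frequencies.")
  list(pool = pool, freq = pmax(freq, 0))
}

#' Simulate genotype dosages on a pedigree with local LD
#'
#' Founder haplotypes are drawn per LD block from a small haplotype pool
#' whose frequencies match the target minor allele frequencies; offspring
#' genotypes are produced by gene dropping (each child inherits one of each
#' parent's two block haplotypes, independently per block, i.e. free
#' recombination between blocks and none within). Dosage is the effect-allele
#' count in `{0, 1, 2}`.
#'
#' @param ped Pedigree tibble.
#' @param variants Variant specification from [variant_spec()].
#' @param seed Optional integer seed.
#' @return An object of class `geno_matrix`: a list with `dosage`
#'   (samples x variants numeric matrix, dimnames set) and `variants` (the
#'   spec tibble plus `ea`, `oa` allele labels and the realized effect-allele
#'   frequency `ea_freq` and folded `maf`).
#' @export
simulate_genotypes <- function(ped, variants, seed = NULL) {
  if (any(variants$maf <= 0) || any(variants$maf > 0.5)) {
    abort("`maf` must lie in (0, 0.5].", class = "mqtl_invalid_argument")
  }
  ord <- pedigree_order(ped)
  ped <- ped[ord, ]
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  fi <- ifelse(is.na(ped$father), NA_integer_, idx[ped$father])
  mi <- ifelse(is.na(ped$mother), NA_integer_, idx[ped$mother])
  with_seed_if(seed, {
    dosage <- matrix(NA_real_, n, nrow(variants),
                     dimnames = list(ped$id, variants$id))
    founders <- which(is.na(fi))
    kids <- which(!is.na(fi))  # already in parents-first order
    tab <- table(variants$block)
    single <- names(tab)[tab == 1L]
    multi <- names(tab)[tab > 1L]
    if (length(single)) {
      # vectorized gene dropping across all independent (1-variant) blocks
      vs <- which(variants$block %in% single)
      m <- length(vs)
      mafs <- variants$maf[vs]
      h1 <- matrix(FALSE, n, m); h2 <- matrix(FALSE, n, m)
      h1[founders, ] <- matrix(runif(length(founders) * m), ncol = m) <
        matrix(mafs, length(founders), m, byrow = TRUE)
      h2[founders, ] <- matrix(runif(length(founders) * m), ncol = m) <
        matrix(mafs, length(founders), m, byrow = TRUE)
      for (i in kids) {
        pf <- runif(m) < 0.5
        h1[i, ] <- ifelse(pf, h1[fi[i], ], h2[fi[i], ])
        pm <- runif(m) < 0.5
        h2[i, ] <- ifelse(pm, h1[mi[i], ], h2[mi[i], ])
      }
      dosage[, vs] <- h1 + h2
    }
    for (b in multi) {
      vb <- which(variants$block == b)
      bp <- block_pool(variants$maf[vb])
      P <- nrow(bp$pool)
      # two haplotype (pool-index) vectors per individual
      hap1 <- integer(n); hap2 <- integer(n)
      hap1[founders] <- sample.int(P, length(founders), TRUE, prob = bp$freq)
      hap2[founders] <- sample.int(P, length(founders), TRUE, prob = bp$freq)
      for (i in kids) {
        hap1[i] <- if (runif(1) < 0.5) hap1[fi[i]] else hap2[fi[i]]
        hap2[i] <- if (runif(1) < 0.5) hap1[mi[i]] else hap2[mi[i]]
      }
      dosage[, vb] <- bp$pool[hap1, , drop = FALSE] +
        bp$pool[hap2, , drop = FALSE]
    }
    ea_freq <- unname(colMeans(dosage) / 2)
    vt <- variants
    vt$ea <- "A"; vt$oa <- "G"
    vt$ea_freq <- ea_freq
    vt$maf <- pmin(ea_freq, 1 - ea_freq)
    structure(list(dosage = dosage, variants = vt), class = "geno_matrix")
  })
}

#' @exportS3Method base::print
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", nrow(x$dosage), " samples x ", ncol(x$dosage),
      " variants\n", sep = "")
  print(head(x$variants), ...)
  invisible(x)
}

#' @exportS3Method base::dim
dim.geno_matrix <- function(x) dim(x$dosage)

#' Dosage TSV input/output
#'
#' Samples-by-variants dosage tables: first column `id` (sample id), one
#' numeric column per variant.
#'
#' @param gm A `geno_matrix` (or bare dosage matrix with dimnames).
#' @param path File path.
#' @return `write_dosage_tsv()` returns `path` invisibly;
#'   `read_dosage_tsv()` returns a `geno_matrix` (with minimal metadata).
#' @export
write_dosage_tsv <- function(gm, path) {
  d <- if (inherits(gm, "geno_matrix")) gm$dosage else gm
  out <- tibble::as_tibble(d, rownames = "id")
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  d <- as.matrix(raw[-1])
  rownames(d) <- raw$id
  ea_freq <- colMeans(d, na.rm = TRUE) / 2
  vt <- tibble::tibble(id = colnames(d), chr = NA_integer_, pos = NA_integer_,
                       maf = pmin(ea_freq, 1 - ea_freq), block = NA_character_,
                       ea = "A", oa = "G", ea_freq = ea_freq)
  structure(list(dosage = d, variants = vt), class = "geno_matrix")
}

#' Minimal VCF input/output with dosages
#'
#' Writes genotypes as a VCF with `GT:DS` sample fields (hard calls from
#' rounded dosage plus the dosage itself) through the vcfR package, and reads
#' the `DS` field back into a `geno_matrix`.
#'
#' @param gm A `geno_matrix`.
#' @param path Output path; `.vcf.gz` is appended when missing (the file is
#'   written gzip-compressed).
#' @return `write_vcf_dosage()` returns the written path invisibly;
#'   `read_vcf_dosage()` returns a `geno_matrix`.
#' @export
write_vcf_dosage <- function(gm, path) {
  if (!grepl("\\.vcf\\.gz$", path)) {
    path <- sub("\\.vcf$", "", path)
    path <- paste0(path, ".vcf.gz")
  }
  d <- gm$dosage; vt <- gm$variants
  n <- nrow(d); m <- ncol(d)
  fix <- cbind(CHROM = as.character(vt$chr), POS = as.character(vt$pos),
               ID = vt$id, REF = vt$oa, ALT = vt$ea, QUAL = ".",
               FILTER = "PASS", INFO = ".")
  hard <- round(t(d))
  gt_code <- matrix(c("0/0", "0/1", "1/1")[hard + 1L], m, n)
  gt <- matrix(paste0(gt_code, ":", signif(t(d), 6)), m, n,
               dimnames = list(NULL, rownames(d)))
  gt <- cbind(FORMAT = "GT:DS", gt)
  v <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")),
                    meta = c("##fileformat=VCFv4.2",
                             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                             "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">"),
                    fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' @rdname write_vcf_dosage
#' @export
read_vcf_dosage <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  d <- t(ds)
  colnames(d) <- vcfR::getID(v)
  ea_freq <- colMeans(d, na.rm = TRUE) / 2
  vt <- tibble::tibble(id = colnames(d),
                       chr = suppressWarnings(as.integer(vcfR::getCHROM(v))),
                       pos = as.integer(vcfR::getPOS(v)),
                       maf = pmin(ea_freq, 1 - ea_freq),
                       block = NA_character_,
                       ea = vcfR::getALT(v), oa = vcfR::getREF(v),
                       ea_freq = ea_freq)
  structure(list(dosage = d, variants = vt), class = "geno_matrix")
}
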