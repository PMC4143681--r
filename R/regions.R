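#' Read a VCF into a dosage matrix
#'
#' Parses a VCF v4.x with GT calls into an individuals x variants dosage
#' matrix (count of alternate alleles). Multiallelic records are rejected
#' with a logged count; missing genotypes are an error (the pipeline
#' assumes complete data). Folded MAFs are recomputed from the dosages.
#'
#' @param path VCF file (plain text or gzipped).
#' @return List of class `genotype_matrix`: `G` (dosage matrix with id row
#'   names), `variants` (`data.frame` with `chrom`, `pos`, `id`, `maf`),
#'   `ids`.
#' @export
read_vcf_dosage <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  as_fix_matrix <- function(f)
    if (is.null(dim(f))) matrix(f, nrow = 1, dimnames = list(NULL, names(f)))
    else f
  fix <- as_fix_matrix(vcfR::getFIX(v))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    message(sprintf("read_vcf_dosage: rejected %d multiallelic records", sum(multi)))
    v <- v[!multi, ]
    fix <- as_fix_matrix(vcfR::getFIX(v))
  }
  if (nrow(fix) == 0L) stop("no biallelic records in VCF")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (anyNA(gt)) stop("missing GT calls are not supported")
  dos <- matrix(0L, nrow = nrow(gt), ncol = ncol(gt))
  dos <- dos + (substr(gt, 1, 1) == "1") + (substr(gt, 3, 3) == "1")
  malformed <- !grepl("^[01][/|][01]$", gt)
  if (any(malformed)) {
    bad <- which(malformed, arr.ind = TRUE)[1, ]
    stop(sprintf("malformed GT at record %d, sample %d: '%s'",
                 bad[1], bad[2], gt[malformed][1]))
  }
  G <- t(dos)
  storage.mode(G) <- "integer"
  rownames(G) <- colnames(gt)
  p <- colMeans(G) / 2
  variants <- data.frame(
    chrom = sub("^chr", "", fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                sprintf("%s:%s", fix[, "CHROM"], fix[, "POS"]), fix[, "ID"]),
    maf = pmin(p, 1 - p),
    stringsAsFactors = FALSE
  )
  colnames(G) <- variants$id
  structure(list(G = G, variants = variants, ids = rownames(G)),
            class = "genotype_matrix")
}

#' Write a dosage matrix as a minimal VCF v4.2
#'
#' Emits biallelic records with unphased GT calls (`0/0`, `0/1`, `1/1`)
#' reconstructing the dosages exactly, so a write/read round trip through
#' [read_vcf_dosage()] is bit-identical.
#'
#' @param path Output file.
#' @param G Dosage matrix (individuals x variants, 0/1/2).
#' @param variants `data.frame` with `chrom`, `pos` and optionally `id`.
#' @export
write_vcf_dosage <- function(path, G, variants) {
  stopifnot(nrow(variants) == ncol(G))
  ids <- rownames(G)
  vid <- if ("id" %in% names(variants)) variants$id else
    sprintf("%s:%d", variants$chrom, variants$pos)
  gt <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(ncol(G)), function(j) {
    paste(c(variants$chrom[j], variants$pos[j], vid[j], "A", "T", ".",
            "PASS", ".", "GT", gt[G[, j] + 1L]), collapse = "\t")
  }, "")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=glsskat",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Construct flanked gene regions
#'
#' A gene region spans 20 kb up- and downstream of the transcript start and
#' stop (1-based inclusive coordinates), clipped at position 1. Overlapping
#' regions are allowed; a variant may belong to several genes.
#'
#' @param genes `data.frame` with `gene`, `chrom`, `start`, `stop`
#'   (1-based inclusive transcript span).
#' @param flank Flank length in base pairs (default 20,000).
#' @return The gene table with added `region_start` and `region_end`.
#' @export
build_regions <- function(genes, flank = 20000L) {
  req <- c("gene", "chrom", "start", "stop")
  miss <- setdiff(req, names(genes))
  if (length(miss)) stop("gene table lacks columns: ", paste(miss, collapse = ", "))
  if (any(genes$start > genes$stop))
    stop("gene annotation error: start > stop for ",
         paste(genes$gene[genes$start > genes$stop], collapse = ", "))
  genes$chrom <- sub("^chr", "", as.character(genes$chrom))
  genes$region_start <- pmax(1L, as.integer(genes$start) - as.integer(flank))
  genes$region_end <- as.integer(genes$stop) + as.integer(flank)
  genes
}

#' Assign variants to gene regions
#'
#' A variant belongs to a region iff `region_start <= pos <= region_end`
#' on the same (chr-prefix-normalized) chromosome. No MAF filtering is
#' performed here: rare and common variants alike enter the region test.
#' Empty regions are retained and flagged.
#'
#' @param regions Output of [build_regions()].
#' @param variants Variant table with `chrom` and `pos`.
#' @return List (one element per region row) of integer variant indices
#'   into `variants`; zero-length entries mark empty regions.
#' @export
assign_variants <- function(regions, variants) {
  vchrom <- sub("^chr", "", as.character(variants$chrom))
  out <- vector("list", nrow(regions))
  any_hit <- FALSE
  for (ch in unique(regions$chrom)) {
    vsel <- which(vchrom == ch)
    rsel <- which(regions$chrom == ch)
    if (length(vsel) == 0L) { out[rsel] <- list(integer()); next }
    ord <- vsel[order(variants$pos[vsel])]
    pos <- variants$pos[ord]
    for (r in rsel) {
      lo <- findInterval(regions$region_start[r] - 0.5, pos) + 1L
      hi <- findInterval(regions$region_end[r] + 0.5, pos)
      out[[r]] <- if (hi >= lo) ord[lo:hi] else integer()
      if (hi >= lo) any_hit <- TRUE
    }
  }
  if (!any_hit && nrow(regions) > 0 && nrow(variants) > 0)
    warning("no variants assigned to any region; check chromosome naming")
  out
}

#' Read a gene annotation table
#'
#' Tab-separated table with columns `gene`, `chrom`, `start`, `stop`.
#' Coordinates are treated as 1-based inclusive by default; set
#' `zero_based_half_open = TRUE` for BED-dialect inputs, which are
#' converted on read (`start + 1`, `stop` unchanged).
#'
#' @param path File path.
#' @param zero_based_half_open Is the input in BED coordinate dialect?
#' @return `data.frame` with 1-based inclusive `start` / `stop`.
#' @export
read_gene_table <- function(path, zero_based_half_open = FALSE) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  miss <- setdiff(c("gene", "chrom", "start", "stop"), names(tb))
  if (length(miss)) stop("gene table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (zero_based_half_open) tb$start <- tb$start + 1L
  tb$chrom <- as.character(tb$chrom)
  tb
}

#' Bonferroni per-test alpha for a family-wise error rate
#'
#' @param n_genes Number of gene regions tested (>= 1).
#' @param fwer Target family-wise error rate.
#' @return List with `raw` (`fwer / n_genes`) and `rounded` (2 significant
#'   figures, the conventionally reported threshold).
#' @examples
#' bonferroni_threshold(1247)  # raw 4.009e-05, reported 4.0e-05
#' @export
bonferroni_threshold <- function(n_genes, fwer = 0.05) {
  stopifnot(n_genes >= 1)
  raw <- fwer / n_genes
  list(raw = raw, rounded = signif(raw, 2))
}

## ---- plain-text table readers/writers used by the simulator and CLI ----

#' Write / read a PED-style pedigree table
#'
#' Six-column whitespace-delimited table (family, individual, father,
#' mother, sex, phenotype placeholder); `0` encodes an absent parent.
#'
#' @param ped Pedigree `data.frame` ([build_pedigrees()]).
#' @param path File path.
#' @return `write_ped_table` the path; `read_ped_table` a pedigree
#'   `data.frame` with a reconstructed `generation` index.
#' @export
write_ped_table <- function(ped, path) {
  out <- data.frame(
    family = ped$family, id = ped$id,
    father = ifelse(is.na(ped$father), "0", ped$father),
    mother = ifelse(is.na(ped$mother), "0", ped$mother),
    sex = ped$sex, phenotype = 0
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_ped_table
#' @export
read_ped_table <- function(path) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  ped <- data.frame(
    id = tb$id, family = tb$family,
    father = ifelse(tb$father == "0", NA_character_, tb$father),
    mother = ifelse(tb$mother == "0", NA_character_, tb$mother),
    sex = as.integer(tb$sex),
    stringsAsFactors = FALSE
  )
  ped$generation <- infer_generations(ped)
  validate_pedigree(ped)
  ped
}

## Topological generation index by iterative peeling; errors on cycles.
infer_generations <- function(ped) {
  n <- nrow(ped)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  gen <- rep(NA_integer_, n)
  gen[is.na(fa) & is.na(mo)] <- 0L
  repeat {
    todo <- which(is.na(gen))
    if (!length(todo)) break
    progressed <- FALSE
    for (i in todo) {
      gf <- if (is.na(fa[i])) -1L else gen[fa[i]]
      gm <- if (is.na(mo[i])) -1L else gen[mo[i]]
      if (!anyNA(c(gf, gm))) {
        gen[i] <- max(gf, gm) + 1L
        progressed <- TRUE
      }
    }
    if (!progressed) stop("pedigree contains a cycle or unresolvable parents")
  }
  gen
}

#' Write a full simulated replicate to disk
#'
#' Emits the file set consumed by the `run` pipeline: VCF genotypes,
#' PED-style pedigree, phenotype + covariate TSV, gene table TSV (1-based
#' inclusive coordinates) and a causal-variant TSV (header only when there
#' are no causal variants).
#'
#' @param dir Output directory (created if needed).
#' @param replicate A replicate as returned by [simulate_replicate()].
#' @return Named character vector of the five file paths.
#' @export
write_replicate <- function(dir, replicate) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    ped = file.path(dir, "pedigree.ped"),
    pheno = file.path(dir, "phenotypes.tsv"),
    genes = file.path(dir, "genes.tsv"),
    causal = file.path(dir, "causal.tsv")
  )
  write_vcf_dosage(paths["vcf"], replicate$G, replicate$variants)
  write_ped_table(replicate$ped, paths["ped"])
  utils::write.table(replicate$phenotypes, paths["pheno"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(replicate$genes[, c("gene", "chrom", "start", "stop")],
                     paths["genes"], sep = "\t", quote = FALSE, row.names = FALSE)
  causal <- replicate$causal
  if (is.null(causal)) causal <- data.frame(chrom = character(), pos = integer())
  utils::write.table(causal, paths["causal"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
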