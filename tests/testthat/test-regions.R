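test_that("region construction applies and clips the 20 kb flanks", {
  genes <- data.frame(gene = c("g1", "g2"), chrom = "3",
                      start = c(50000L, 5000L), stop = c(60000L, 9000L))
  rg <- build_regions(genes)
  expect_equal(rg$region_start, c(30000L, 1L))
  expect_equal(rg$region_end, c(80000L, 29000L))
  bad <- data.frame(gene = "g", chrom = "3", start = 10L, stop = 5L)
  expect_error(build_regions(bad), "start > stop")
})

test_that("variant assignment is inclusive, overlap-aware and oracle-exact", {
  genes <- data.frame(gene = c("g1", "g2"), chrom = "3",
                      start = c(100000L, 110000L), stop = c(101000L, 111000L))
  rg <- build_regions(genes)
  v <- data.frame(chrom = "3",
                  pos = c(80000L, 79999L, 121000L, 121001L, 105000L))
  idx <- assign_variants(rg, v)
  expect_true(1L %in% idx[[1]])        # exactly at region start
  expect_false(2L %in% idx[[1]])       # 1 bp outside
  expect_true(3L %in% idx[[1]])        # exactly at region end
  expect_false(4L %in% idx[[1]])
  ## 10 kb-apart genes share the variant between both regions
  expect_true(5L %in% idx[[1]] && 5L %in% idx[[2]])
  ## chromosome naming is normalized; mismatch everywhere warns
  v2 <- transform(v, chrom = "chr3")
  expect_equal(assign_variants(rg, v2), idx)
  v3 <- transform(v, chrom = "7")
  expect_warning(z <- assign_variants(rg, v3), "chromosome")
  expect_true(all(lengths(z) == 0))
})

test_that("assignment equals a brute-force double loop on random inputs", {
  set.seed(14)
  for (k in 1:8) {
    genes <- data.frame(gene = sprintf("g%d", 1:12),
                        chrom = sample(c("1", "2"), 12, replace = TRUE),
                        start = sample.int(5e5, 12))
    genes$stop <- genes$start + sample.int(3e4, 12)
    rg <- build_regions(genes, flank = 5000)
    v <- data.frame(chrom = sample(c("1", "2"), 200, replace = TRUE),
                    pos = sample.int(6e5, 200))
    idx <- assign_variants(rg, v)
    brute <- lapply(seq_len(nrow(rg)), function(r)
      which(v$chrom == rg$chrom[r] & v$pos >= rg$region_start[r] &
              v$pos <= rg$region_end[r]))
    expect_equal(lapply(idx, sort), brute)
  }
  ## empty regions are retained: one result slot per annotation row
  expect_length(assign_variants(build_regions(
    data.frame(gene = sprintf("g%d", 1:1247), chrom = "3",
               start = seq(1e6, by = 1e5, length.out = 1247),
               stop = seq(1e6, by = 1e5, length.out = 1247) + 10)),
    data.frame(chrom = "3", pos = 1e6)), 1247)
})

test_that("region order does not matter and construction is idempotent", {
  genes <- data.frame(gene = sprintf("g%d", 1:6), chrom = "3",
                      start = seq(1e5, by = 2e5, length.out = 6))
  genes$stop <- genes$start + 30000L
  rg <- build_regions(genes)
  expect_equal(build_regions(rg)[, names(rg)], rg)  # idempotent
  shuf <- sample(6)
  rg2 <- build_regions(genes[shuf, ])
  expect_equal(rg2$region_start, rg$region_start[shuf])
})

test_that("the Bonferroni threshold matches its reported precision", {
  b <- bonferroni_threshold(1247)
  expect_equal(b$rounded, 4.0e-5)
  expect_equal(b$raw, 0.05 / 1247)
  expect_equal(bonferroni_threshold(1)$raw, 0.05)
  expect_equal(bonferroni_threshold(1000)$rounded, 5.0e-5)
})

test_that("VCF writing and reading round-trip the dosage matrix exactly", {
  cfg <- tiny_config()
  rep1 <- simulate_replicate(cfg, seed = 103)
  tmp <- tempfile(fileext = ".vcf")
  write_vcf_dosage(tmp, rep1$G, rep1$variants)
  gm <- read_vcf_dosage(tmp)
  expect_identical(unname(gm$G), unname(rep1$G))
  expect_identical(rownames(gm$G), rownames(rep1$G))
  expect_equal(gm$variants$pos, rep1$variants$pos)
  ## recomputed MAFs are folded
  expect_true(all(gm$variants$maf >= 0 & gm$variants$maf <= 0.5))
})

test_that("multiallelic and malformed records are handled explicitly", {
  tmp <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2"), collapse = "\t"),
    "3\t100\tv1\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1",
    "3\t200\tv2\tA\tT,C\t.\tPASS\t.\tGT\t0/0\t1/2",
    "3\t300\tv3\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/0"
  ), tmp)
  expect_message(gm <- read_vcf_dosage(tmp), "1 multiallelic")
  expect_equal(ncol(gm$G), 2)
  ## all-reference record: MAF 0 (monomorphic, flagged by its frequency)
  expect_equal(gm$variants$maf[gm$variants$pos == 300], 0)
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1"), collapse = "\t"),
    "3\t100\tv1\tA\tT\t.\tPASS\t.\tGT\t./."
  ), tmp)
  expect_error(read_vcf_dosage(tmp), "missing GT")
})

test_that("gene tables read in either coordinate dialect", {
  tmp <- tempfile(fileext = ".tsv")
  write.table(data.frame(gene = "g1", chrom = "3", start = 99L, stop = 200L),
              tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  one <- read_gene_table(tmp)
  expect_equal(one$start, 99L)
  bed <- read_gene_table(tmp, zero_based_half_open = TRUE)
  expect_equal(bed$start, 100L)          # BED start 99 is 1-based 100
  expect_equal(bed$stop, 200L)           # half-open end == inclusive stop
  write.table(data.frame(g = 1), tmp, sep = "\t", row.names = FALSE)
  expect_error(read_gene_table(tmp), "lacks columns")
})

test_that("PED tables round-trip and cycles are rejected", {
  ped <- build_pedigrees(3)
  tmp <- tempfile(fileext = ".ped")
  write_ped_table(ped, tmp)
  back <- read_ped_table(tmp)
  expect_equal(back$id, ped$id)
  expect_equal(back$father, ped$father)
  expect_equal(back$generation, ped$generation)
  ## a parent loop cannot be ordered into generations
  cyc <- data.frame(family = "f", id = c("a", "b"), father = c("b", "a"),
                    mother = c("0", "0"), sex = c(1, 1), phenotype = 0)
  write.table(cyc, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_ped_table(tmp), "cycle")
})

test_that("write_replicate emits the full, round-trippable file set", {
  cfg <- tiny_config()
  rep1 <- simulate_replicate(cfg, seed = 104)
  dir <- file.path(tempdir(), "rep_out")
  paths <- write_replicate(dir, rep1)
  expect_true(all(file.exists(paths)))
  ## VCF record count equals the variant count
  nrec <- sum(!startsWith(readLines(paths["vcf"]), "#"))
  expect_equal(nrec, nrow(rep1$variants))
  ## null replicate: causal file has a header and nothing else
  causal <- read.table(paths["causal"], header = TRUE, sep = "\t")
  expect_equal(nrow(causal), 0)
  ## dosages survive the round trip bit-exactly
  gm <- read_vcf_dosage(paths["vcf"])
  expect_identical(unname(gm$G), unname(rep1$G))
  unlink(dir, recursive = TRUE)
})
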