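keyset <- function(vcf) vapply(vcf$variants, variant_key, character(1))

test_that("physical location filter partitions the input and matches a scan oracle", {
  vars <- random_variant_set(1000)
  vcf <- mk_vcf(vars)
  set.seed(9)
  regions <- data.frame(chrom = sample(c("1", "2", "X"), 5, replace = TRUE),
                        start = sample(40000L, 5))
  regions$end <- regions$start + sample(2000:8000, 5)
  kept <- filter_physical_location(vcf, regions, "keep")
  dropped <- filter_physical_location(vcf, regions, "discard")
  oracle <- vapply(vars, function(v) {
    hit <- FALSE
    for (r in seq_len(nrow(regions)))
      if (regions$chrom[r] == v$chrom && v$pos >= regions$start[r] &&
          v$pos <= regions$end[r]) hit <- TRUE
    hit
  }, logical(1))
  expect_identical(keyset(kept), keyset(mk_vcf(vars[oracle])))
  expect_identical(n_variants(kept) + n_variants(dropped), length(vars))
  expect_length(intersect(keyset(kept), keyset(dropped)), 0)
  expect_identical(n_variants(filter_physical_location(mk_vcf(list()), regions)), 0L)
})

test_that("read depth filter evaluates the quantified predicate in both scopes", {
  vars <- random_variant_set(400, seed = 21)
  vcf <- mk_vcf(vars)
  for (scope in c("any_sample", "all_samples")) {
    got <- filter_read_depth(vcf, 10, scope)
    oracle <- vapply(vars, function(v) {
      dp <- v$calls$S1$depth
      !is.na(dp) && dp >= 10
    }, logical(1))  # single sample: scopes coincide
    expect_identical(keyset(got), keyset(mk_vcf(vars[oracle])))
  }
  expect_identical(n_variants(filter_read_depth(vcf, 0)), length(vars))
  one <- mk_vcf(list(mk_variant(dp = 9)))
  expect_identical(n_variants(filter_read_depth(one, 10)), 0L)
})

test_that("call quality filter is strictly greater-than and missing QUAL fails", {
  expect_identical(n_variants(filter_call_quality(
    mk_vcf(list(mk_variant(qual = 20))), 20)), 0L)
  expect_identical(n_variants(filter_call_quality(
    mk_vcf(list(mk_variant(qual = 20.01))), 20)), 1L)
  expect_identical(n_variants(filter_call_quality(
    mk_vcf(list(mk_variant(qual = NA))), 0)), 0L)
  vars <- random_variant_set(400, seed = 5)
  got <- filter_call_quality(mk_vcf(vars), 30)
  oracle <- vapply(vars, function(v) !is.na(v$qual) && v$qual > 30, logical(1))
  expect_identical(keyset(got), keyset(mk_vcf(vars[oracle])))
})

test_that("mutation type filter matches any annotation but keeps all of them", {
  v_mixed <- mk_variant(pos = 1L)
  v_mixed$ann <- data.frame(alt = "G", gene = c("A1", "A1"),
                            tx_id = c("NM_1", "NM_2"), region = "exon",
                            cdna = NA_character_, mut = c("synonymous", "missense"),
                            aa = NA_character_, iso = NA_character_,
                            refseq = NA_character_, domain = NA_character_,
                            stringsAsFactors = FALSE)
  v_syn <- mk_variant(pos = 2L)
  v_syn$ann <- v_mixed$ann[1, ]
  vcf <- mk_vcf(list(v_mixed, v_syn))
  got <- filter_mutation_type(vcf, c("missense", "nonsense"))
  expect_identical(n_variants(got), 1L)
  expect_identical(nrow(got$variants[[1]]$ann), 2L)  # annotations retained
  all_types <- c("synonymous", "missense", "nonsense", "stoploss",
                 "frameshift", "inframe_indel", "noncoding")
  expect_identical(n_variants(filter_mutation_type(vcf, all_types)), 2L)
  bare <- mk_vcf(list(mk_variant()))
  expect_error(filter_mutation_type(bare, "missense"), "annotate")
  # region classes are selectable alongside mutation types
  v_spl <- mk_variant(pos = 3L)
  v_spl$ann <- v_mixed$ann[1, ]
  v_spl$ann$region <- "splice_donor"; v_spl$ann$mut <- "noncoding"
  expect_identical(n_variants(filter_mutation_type(mk_vcf(list(v_spl)),
                                                   "splice_donor")), 1L)
})

test_that("AAF filter applies a strict rarity bound with an absent-variant policy", {
  tab_file <- tempfile()
  writeLines(c("1\t100\tA\tG\t0.009", "1\t200\tA\tG\t0.01", "1\t300\tA\tG\t0.25"),
             tab_file)
  tab <- load_aaf_table(tab_file)
  vcf <- mk_vcf(list(mk_variant(pos = 100L), mk_variant(pos = 200L),
                     mk_variant(pos = 300L), mk_variant(pos = 400L)))
  kept <- filter_aaf(vcf, tab, 0.01)
  expect_identical(vapply(kept$variants, function(v) v$pos, integer(1)),
                   c(100L, 400L))
  dropped_absent <- filter_aaf(vcf, tab, 0.01, absent_policy = "drop")
  expect_identical(vapply(dropped_absent$variants, function(v) v$pos, integer(1)), 100L)
  expect_equal(aaf_lookup(tab, "1", 300, "A", "G"), 0.25)
  expect_true(is.na(aaf_lookup(tab, "1", 999, "A", "G")))
})

test_that("novelty filter partitions on rsID and table membership", {
  tab_file <- tempfile()
  writeLines("1\t500\tA\tG\t0.2", tab_file)
  tab <- load_aaf_table(tab_file)
  vars <- list(mk_variant(pos = 100L, id = "rs1"),
               mk_variant(pos = 500L),             # anonymous but in the table
               mk_variant(pos = 900L))             # truly novel
  vcf <- mk_vcf(vars)
  novel <- filter_novel(vcf, tab, "keep_novel")
  known <- filter_novel(vcf, tab, "keep_known")
  expect_identical(vapply(novel$variants, function(v) v$pos, integer(1)), 900L)
  expect_identical(vapply(known$variants, function(v) v$pos, integer(1)),
                   c(100L, 500L))
  expect_identical(n_variants(novel) + n_variants(known), 3L)
})

test_that("same-variant filter equals the key-intersection oracle over 4 files", {
  set.seed(31)
  pool <- random_variant_set(120, seed = 31)
  files <- lapply(1:4, function(i) mk_vcf(sample(pool, 80)))
  got <- filter_same_variant(files)
  oracle <- Reduce(intersect, lapply(files, keyset))
  for (i in 1:4) expect_setequal(keyset(got[[i]]), intersect(keyset(files[[i]]), oracle))
  same <- filter_same_variant(list(files[[1]], files[[1]]))
  expect_identical(keyset(same[[1]]), keyset(files[[1]]))
  expect_error(filter_same_variant(files[1]), "at least 2")
})

test_that("same-gene filter shares by gene symbol, not variant identity", {
  a <- zyg_vcf("A", "HET", pos = 100L, gene = "G1")
  b <- zyg_vcf("B", "HET", pos = 200L, gene = "G1")
  got <- filter_same_gene(list(a, b))
  expect_identical(n_variants(got[[1]]), 1L)
  expect_identical(n_variants(got[[2]]), 1L)
  c2 <- zyg_vcf("C", "HET", pos = 300L, gene = "G2")
  got2 <- filter_same_gene(list(a, c2))
  expect_identical(n_variants(got2[[1]]), 0L)
  expect_identical(n_variants(got2[[2]]), 0L)
  # oracle: per-file gene sets intersected
  files <- lapply(1:4, function(i) mk_vcf(sample(random_variant_set(150, seed = i), 100)))
  got3 <- filter_same_gene(files)
  gene_sets <- lapply(files, function(f)
    unique(unlist(lapply(f$variants, function(v) if (is.null(v$ann)) NULL else v$ann$gene))))
  shared <- Reduce(intersect, gene_sets)
  for (i in 1:4) {
    oracle <- vapply(files[[i]]$variants, function(v)
      !is.null(v$ann) && any(v$ann$gene %in% shared), logical(1))
    expect_identical(keyset(got3[[i]]), keyset(files[[i]])[oracle])
  }
})

test_that("single-file filters are idempotent contractions and order-independent", {
  vars <- random_variant_set(500, seed = 13)
  vcf <- mk_vcf(vars)
  tab_file <- tempfile()
  writeLines("1\t1\tA\tG\t0.5", tab_file)
  tab <- load_aaf_table(tab_file)
  filters <- list(
    q = function(v) filter_call_quality(v, 25),
    d = function(v) filter_read_depth(v, 12),
    n = function(v) filter_novel(v, tab, "keep_novel"))
  applied <- lapply(filters, function(f) f(vcf))
  for (i in seq_along(filters)) {
    one <- applied[[i]]
    expect_true(all(keyset(one) %in% keyset(vcf)))
    expect_identical(keyset(filters[[i]](one)), keyset(one))
  }
  perms <- list(c(1, 2, 3), c(3, 2, 1), c(2, 3, 1))
  results <- lapply(perms, function(p) {
    out <- vcf
    for (i in p) out <- filters[[i]](out)
    keyset(out)
  })
  expect_identical(results[[1]], results[[2]])
  expect_identical(results[[1]], results[[3]])
})

test_that("BED regions convert to 1-based inclusive at load", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("track name=test", "chr1\t99\t200", "chrX\t0\t10"), f)
  bed <- read_bed(f)
  expect_identical(bed$start, c(100L, 1L))
  expect_identical(bed$end, c(200L, 10L))
})
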