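test_that("refGene coordinates convert from 0-based half-open to 1-based inclusive", {
  # txStart=999 / exonStarts="999," in file coordinates -> exon starts at 1000
  row <- paste("NM_1", "1", "+", 999, 1400, 1049, 1349, 1,
               "999,", "1400,", 0, "GENEA", sep = "\t")
  txs <- load_gene_map(write_gene_map(row))
  expect_length(txs, 1)
  tx <- txs[[1]]
  expect_identical(tx$tx_start, 1000L)
  expect_identical(tx$tx_end, 1400L)
  expect_identical(unname(tx$exons[1, ]), c(1000L, 1400L))
  expect_identical(tx$cds_start, 1050L)
  expect_identical(tx$cds_end, 1349L)
  expect_true(tx$is_reference_isoform)

  expect_length(load_gene_map(write_gene_map(character())), 0)
})

test_that("a minus-strand multi-exon row converts to hand-computed intervals", {
  row <- refgene_row("NM_9", "2", "-",
                     list(c(101, 200), c(301, 400), c(501, 600)),
                     150, 550, "GENEB")
  tx <- load_gene_map(write_gene_map(row))[[1]]
  expect_identical(tx$strand, "-")
  expect_identical(unname(tx$exons),
                   matrix(c(101L, 301L, 501L, 200L, 400L, 600L), ncol = 2))
  expect_identical(c(tx$cds_start, tx$cds_end), c(150L, 550L))
})

test_that("malformed gene-map rows raise parse/validation errors", {
  bad_len <- paste("NM_1", "1", "+", 0, 100, 10, 90, 2,
                   "0,50,", "40,", 0, "G", sep = "\t")
  expect_error(load_gene_map(write_gene_map(bad_len)), "mismatch")
  bad_cds <- paste("NM_1", "1", "+", 100, 200, 10, 190, 1,
                   "100,", "200,", 0, "G", sep = "\t")
  expect_error(load_gene_map(write_gene_map(bad_cds)), "CDS outside")
})

test_that("region carving places splice windows and promoters where expected", {
  # plus strand, 2 exons 101-200 / 301-400, CDS 121-380, splice_bp=5
  row <- refgene_row("NM_1", "1", "+", list(c(101, 200), c(301, 400)),
                     121, 380, "G1")
  map <- build_region_map(load_gene_map(write_gene_map(row)),
                          gene_map_params(promoter_bp = 50, splice_bp = 5))
  reg_at <- function(p) query_regions(map, "1", p)$region
  expect_identical(reg_at(150), "exon")
  expect_identical(reg_at(110), "utr5")
  expect_identical(reg_at(390), "utr3")
  # the 5 bases after exon 1 are donor, the 5 before exon 2 acceptor
  for (p in 201:205) expect_identical(reg_at(p), "splice_donor")
  for (p in 296:300) expect_identical(reg_at(p), "splice_acceptor")
  expect_identical(reg_at(250), "intron")
  expect_identical(reg_at(100), "promoter_up")
  expect_identical(reg_at(51), "promoter_up")
  expect_identical(reg_at(450), "promoter_down")
  expect_identical(nrow(query_regions(map, "1", 50)), 0L)   # beyond promoter
  expect_identical(nrow(query_regions(map, "1", 1500)), 0L) # intergenic
})

test_that("a single-exon transcript emits no intron or splice intervals", {
  row <- refgene_row("NM_1", "1", "+", list(c(101, 400)), 121, 380, "G1")
  map <- build_region_map(load_gene_map(write_gene_map(row)), gene_map_params())
  regs <- unique(map$index[["1"]]$df$region)
  expect_false(any(c("intron", "splice_donor", "splice_acceptor") %in% regs))
})

test_that("overlapping isoforms each contribute a query hit", {
  rows <- c(refgene_row("NM_1", "1", "+", list(c(101, 200), c(301, 400)), 121, 380, "G1"),
            refgene_row("NM_2", "1", "+", list(c(151, 400)), 171, 380, "G1"))
  map <- build_region_map(load_gene_map(write_gene_map(rows)), gene_map_params())
  hits <- query_regions(map, "1", 180)
  expect_identical(nrow(hits), 2L)
  expect_setequal(hits$tx_id, c("NM_1", "NM_2"))
})

test_that("cDNA labels follow coding, splice-offset and flank conventions", {
  row <- refgene_row("NM_1", "1", "+", list(c(101, 200), c(301, 400)),
                     121, 380, "G1")
  tx <- load_gene_map(write_gene_map(row))[[1]]
  expect_identical(cdna_position(tx, 121), "c.1")
  expect_identical(cdna_position(tx, 200), "c.80")  # last base of exon 1 CDS
  expect_identical(cdna_position(tx, 201), "c.80+1")
  expect_identical(cdna_position(tx, 300), "c.81-1")
  expect_identical(cdna_position(tx, 301), "c.81")
  expect_identical(cdna_position(tx, 120), "c.-1")
  expect_identical(cdna_position(tx, 110), "c.-11")
  expect_identical(cdna_position(tx, 381), "c.*1")
  # promoter positions count the 5'UTR exonic length plus the distance
  # upstream of the transcription start: 20 UTR bases + 67 genomic = c.-87
  expect_identical(cdna_position(tx, 34), "c.-87")
  expect_error(cdna_position(tx, 5000), "out of reach")
  # a transcript with no 5'UTR reproduces the classic promoter numbering:
  # 167 bp upstream of the transcription start is c.-167
  row2 <- refgene_row("NM_2", "1", "+", list(c(201, 500)), 201, 470, "G2")
  tx2 <- load_gene_map(write_gene_map(row2))[[1]]
  expect_identical(cdna_position(tx2, 34), "c.-167")
  expect_identical(query_regions(build_region_map(list(tx2), gene_map_params()),
                                 "1", 34)$region, "promoter_up")
})

test_that("minus-strand cDNA numbering runs against the genome", {
  row <- refgene_row("NM_1", "1", "-", list(c(101, 200), c(301, 400)),
                     121, 380, "G1")
  tx <- load_gene_map(write_gene_map(row))[[1]]
  expect_identical(cdna_position(tx, 380), "c.1")
  expect_identical(cdna_position(tx, 301), "c.80")
  expect_identical(cdna_position(tx, 300), "c.80+1")  # donor side of the intron
  expect_identical(cdna_position(tx, 201), "c.81-1")
  expect_identical(cdna_position(tx, 121), "c.160")  # CDS spans 2 x 80 bases
  expect_identical(cdna_position(tx, 390), "c.-10")
  expect_identical(cdna_position(tx, 450), "c.-70")   # 20 UTR + 50 upstream
})

test_that("query_regions equals the brute-force per-base classifier on random maps", {
  set.seed(11)
  params <- gene_map_params(promoter_bp = 80, splice_bp = 5)
  for (rep in 1:10) {
    txs <- load_gene_map(write_gene_map(random_gene_map(n_tx = 3, chrom_len = 1500)))
    map <- build_region_map(txs, params)
    hits <- varseg:::region_hits(map, "1", 1:1500)
    got <- split(paste(hits$tx, hits$region), hits$pos_index)
    mismatches <- 0L
    for (p in 1:1500) {
      want <- character()
      for (i in seq_along(txs)) {
        for (lab in oracle_region_labels(txs[[i]], p, params))
          want <- c(want, paste(i, lab))
      }
      have <- got[[as.character(p)]]
      if (is.null(have)) have <- character()
      if (!setequal(have, want)) mismatches <- mismatches + 1L
    }
    expect_identical(mismatches, 0L)
  }
})

test_that("disabled region classes are omitted from the map", {
  row <- refgene_row("NM_1", "1", "+", list(c(101, 200), c(301, 400)), 121, 380, "G1")
  params <- gene_map_params(enabled_regions = c("exon", "intron"))
  map <- build_region_map(load_gene_map(write_gene_map(row)), params)
  expect_setequal(unique(map$index[["1"]]$df$region), c("exon", "intron"))
  expect_identical(nrow(query_regions(map, "1", 110)), 0L)  # utr5 disabled
})

test_that("strand flip swaps donor/acceptor and utr5/utr3 labels only", {
  params <- gene_map_params(promoter_bp = 60, splice_bp = 5)
  exons <- list(c(101, 200), c(301, 400))
  fwd <- build_region_map(load_gene_map(write_gene_map(
    refgene_row("NM_1", "1", "+", exons, 121, 380, "G1"))), params)
  rev <- build_region_map(load_gene_map(write_gene_map(
    refgene_row("NM_1", "1", "-", exons, 121, 380, "G1"))), params)
  swap <- c(exon = "exon", intron = "intron",
            splice_donor = "splice_acceptor", splice_acceptor = "splice_donor",
            utr5 = "utr3", utr3 = "utr5",
            promoter_up = "promoter_down", promoter_down = "promoter_up")
  ok <- vapply(seq(41, 460), function(p) {
    f <- query_regions(fwd, "1", p)$region
    r <- query_regions(rev, "1", p)$region
    identical(sort(unname(swap[f])), sort(r))
  }, logical(1))
  expect_true(all(ok))
})

test_that("cached region maps are reused and invalidated by content", {
  row <- refgene_row("NM_1", "1", "+", list(c(101, 400)), 121, 380, "G1")
  path <- write_gene_map(row)
  cache <- tempfile()
  m1 <- cached_region_map(path, gene_map_params(), cache_dir = cache)
  files1 <- list.files(cache)
  m2 <- cached_region_map(path, gene_map_params(), cache_dir = cache)
  expect_identical(list.files(cache), files1)
  expect_equal(m1$index, m2$index)
  cached_region_map(path, gene_map_params(promoter_bp = 100), cache_dir = cache)
  expect_identical(length(list.files(cache)), 2L)
})
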