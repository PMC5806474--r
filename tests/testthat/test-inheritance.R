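ZYGS <- c("HOM_REF", "HET", "HOM_ALT")
carrier <- function(z) z %in% c("HET", "HOM_ALT")

trio_view <- function(fa, mo, ch, ped) {
  vcfs <- list(fa = zyg_vcf("fa", fa, gene = "G1"),
               mo = zyg_vcf("mo", mo, gene = "G1"),
               ch = zyg_vcf("ch", ch, gene = "G1"))
  family_genotype_view(ped, vcfs)
}

test_that("dominant trio decisions match the hand-coded truth table (27 combos)", {
  ped <- trio_ped(father_aff = "affected")  # affected father -> affected child
  for (fa in ZYGS) for (mo in ZYGS) for (ch in ZYGS) {
    got <- length(filter_autosomal_dominant(trio_view(fa, mo, ch, ped))) == 1L
    # complete penetrance: both affecteds carry, unaffected mother does not,
    # and the child's affected parent transmits
    want <- carrier(ch) && carrier(fa) && !carrier(mo)
    expect_identical(got, want,
                     info = sprintf("AD fa=%s mo=%s ch=%s", fa, mo, ch))
  }
})

test_that("de novo trio decisions match the truth table (27 combos)", {
  ped <- trio_ped()  # both parents unaffected
  for (fa in ZYGS) for (mo in ZYGS) for (ch in ZYGS) {
    got <- length(filter_autosomal_dominant(trio_view(fa, mo, ch, ped),
                                            de_novo = TRUE)) == 1L
    want <- carrier(ch) && !carrier(fa) && !carrier(mo)
    expect_identical(got, want,
                     info = sprintf("denovo fa=%s mo=%s ch=%s", fa, mo, ch))
  }
})

test_that("recessive HOM trio decisions match the truth table (27 combos)", {
  ped <- trio_ped()
  for (fa in ZYGS) for (mo in ZYGS) for (ch in ZYGS) {
    res <- filter_autosomal_recessive(trio_view(fa, mo, ch, ped))
    got <- length(res$hom_keys) == 1L
    # affected child homozygous, both genotyped parents heterozygous carriers
    want <- ch == "HOM_ALT" && fa == "HET" && mo == "HET"
    expect_identical(got, want,
                     info = sprintf("AR fa=%s mo=%s ch=%s", fa, mo, ch))
  }
})

quad_ped <- function() {
  mk_ped(c("fa", "mo", "s1", "s2"),
         c(NA, NA, "fa", "fa"), c(NA, NA, "mo", "mo"),
         c("male", "female", "female", "male"),
         c("unaffected", "unaffected", "affected", "affected"))
}

chet_tab <- function(fa1, fa2, mo1, mo2) {
  data.frame(chrom = "1", pos = c(100L, 200L), ref = "A", alt = "G", gene = "G1",
             fa = c(fa1, fa2), mo = c(mo1, mo2),
             s1 = c("HET", "HET"), s2 = c("HET", "HET"),
             stringsAsFactors = FALSE)
}

test_that("compound-het detection requires opposite parental origin", {
  ped <- quad_ped()
  inds <- c("fa", "mo", "s1", "s2")
  # father carries v1 only, mother v2 only -> C-HET gene reported
  view <- family_genotype_view(ped, family_vcfs(chet_tab("HET", "ABSENT", "ABSENT", "HET"), inds))
  res <- filter_autosomal_recessive(view)
  expect_length(res$chet_genes, 1)
  expect_setequal(res$chet_genes[[1]]$keys, c("1:100:A:G", "1:200:A:G"))
  expect_identical(unname(res$chet_genes[[1]]$origin[c("1:100:A:G", "1:200:A:G")]),
                   c("paternal", "maternal"))
  # father carries both -> he would be an unaffected compound het: rejected
  view2 <- family_genotype_view(ped, family_vcfs(chet_tab("HET", "HET", "ABSENT", "HET"), inds))
  expect_length(filter_autosomal_recessive(view2)$chet_genes, 0)
  # ungenotyped parents: degrade gracefully to >=2 shared HETs
  tab3 <- chet_tab("ABSENT", "ABSENT", "ABSENT", "ABSENT")
  view3 <- family_genotype_view(ped, family_vcfs(tab3, inds))
  res3 <- filter_autosomal_recessive(view3)
  expect_length(res3$chet_genes, 1)
  expect_identical(unname(res3$chet_genes[[1]]$origin), c("unknown", "unknown"))
})

test_that("an unaffected homozygote eliminates a recessive candidate", {
  ped <- mk_ped(c("fa", "mo", "s1", "s2"),
                c(NA, NA, "fa", "fa"), c(NA, NA, "mo", "mo"),
                c("male", "female", "female", "male"),
                c("unaffected", "unaffected", "affected", "unaffected"))
  tab <- data.frame(chrom = "1", pos = 100L, ref = "A", alt = "G", gene = "G1",
                    fa = "HET", mo = "HET", s1 = "HOM_ALT", s2 = "HOM_ALT",
                    stringsAsFactors = FALSE)
  view <- family_genotype_view(ped, family_vcfs(tab, c("fa", "mo", "s1", "s2")))
  expect_length(filter_autosomal_recessive(view)$hom_keys, 0)
  tab$s2 <- "HET"  # unaffected carrier is fine
  view2 <- family_genotype_view(ped, family_vcfs(tab, c("fa", "mo", "s1", "s2")))
  expect_identical(filter_autosomal_recessive(view2)$hom_keys, "1:100:A:G")
})

xlr_ped <- function(son_aff = "affected") {
  mk_ped(c("fa", "mo", "son"),
         c(NA, NA, "fa"), c(NA, NA, "mo"),
         c("male", "female", "male"),
         c("unaffected", "unaffected", son_aff))
}

test_that("hemizygous affected males satisfy XLR without a compound partner", {
  ped <- xlr_ped()
  # single HET-coded X call in the affected son
  tab <- data.frame(chrom = "X", pos = 500L, ref = "C", alt = "T", gene = "GX",
                    fa = "ABSENT", mo = "HET", son = "HET", stringsAsFactors = FALSE)
  view <- family_genotype_view(ped, family_vcfs(tab, c("fa", "mo", "son")))
  res <- filter_x_recessive(view)
  expect_identical(res$hom_keys, "X:500:C:T")
  expect_length(res$chet_genes, 0)
  # two HETs in one X gene: still kept via hemizygosity, no C-HET machinery
  tab2 <- data.frame(chrom = "X", pos = c(500L, 600L), ref = "C", alt = "T",
                     gene = "GX", fa = "ABSENT", mo = "HET",
                     son = c("HET", "HET"), stringsAsFactors = FALSE)
  view2 <- family_genotype_view(ped, family_vcfs(tab2, c("fa", "mo", "son")))
  res2 <- filter_x_recessive(view2)
  expect_setequal(res2$hom_keys, c("X:500:C:T", "X:600:C:T"))
  expect_length(res2$chet_genes, 0)
})

test_that("an unaffected male carrying the candidate X allele eliminates it", {
  ped <- xlr_ped()
  tab <- data.frame(chrom = "X", pos = 500L, ref = "C", alt = "T", gene = "GX",
                    fa = "HET", mo = "HET", son = "HOM_ALT", stringsAsFactors = FALSE)
  view <- family_genotype_view(ped, family_vcfs(tab, c("fa", "mo", "son")))
  expect_length(filter_x_recessive(view)$hom_keys, 0)
})

test_that("X filters reject autosomal keys and unknown-sex affecteds", {
  ped <- xlr_ped()
  tab <- data.frame(chrom = "1", pos = 500L, ref = "C", alt = "T", gene = "GX",
                    fa = "ABSENT", mo = "HET", son = "HET", stringsAsFactors = FALSE)
  view <- family_genotype_view(ped, family_vcfs(tab, c("fa", "mo", "son")))
  expect_error(filter_x_recessive(view), "autosomal key")
  ped2 <- xlr_ped(); ped2$sex[3] <- "unknown"
  tabx <- tab; tabx$chrom <- "X"
  view2 <- family_genotype_view(ped2, family_vcfs(tabx, c("fa", "mo", "son")))
  expect_error(filter_x_recessive(view2), "sex")
})

test_that("X-dominant treats HET-coded male calls as carriers", {
  ped <- mk_ped(c("fa", "mo", "son"),
                c(NA, NA, "fa"), c(NA, NA, "mo"),
                c("male", "female", "male"),
                c("unaffected", "affected", "affected"))
  tab <- data.frame(chrom = "X", pos = 700L, ref = "G", alt = "A", gene = "GX",
                    fa = "ABSENT", mo = "HET", son = "HET", stringsAsFactors = FALSE)
  view <- family_genotype_view(ped, family_vcfs(tab, c("fa", "mo", "son")))
  expect_identical(filter_x_dominant(view), "X:700:G:A")
  empty <- family_genotype_view(ped, family_vcfs(tab[0, ], c("fa", "mo", "son")))
  expect_length(filter_x_dominant(empty), 0)
})

test_that("mosaic window is a closed interval on the alternate-allele fraction", {
  fr <- c(0.05, 0.10, 0.20, 0.35, 0.50)
  vars <- lapply(seq_along(fr), function(i)
    mk_variant(pos = i * 10L, ad = c(100 - fr[i] * 100, fr[i] * 100), dp = 100))
  got <- filter_mosaic(mk_vcf(vars))
  expect_identical(vapply(got$variants, function(v) v$pos, integer(1)),
                   c(20L, 30L, 40L))
  expect_error(filter_mosaic(mk_vcf(list(mk_variant(gt = "0/1")))), "read depths")
})

test_that("inheritance filters are contractions over the union of keys", {
  set.seed(17)
  ped <- quad_ped()
  inds <- c("fa", "mo", "s1", "s2")
  tab <- data.frame(chrom = sample(c("1", "2"), 50, replace = TRUE),
                    pos = sample(1e5, 50), ref = "A", alt = "G",
                    gene = sample(sprintf("G%d", 1:8), 50, replace = TRUE),
                    stringsAsFactors = FALSE)
  for (ind in inds) tab[[ind]] <- sample(c(ZYGS, "ABSENT"), 50, replace = TRUE)
  view <- family_genotype_view(ped, family_vcfs(tab, inds))
  all_keys <- rownames(view$zyg)
  ad <- filter_autosomal_dominant(view)
  ar <- filter_autosomal_recessive(view)
  expect_true(all(ad %in% all_keys))
  expect_true(all(ar$hom_keys %in% all_keys))
  expect_true(all(unlist(lapply(ar$chet_genes, `[[`, "keys")) %in% all_keys))
})

test_that("model tags and compound-het partners are written in-line", {
  ped <- quad_ped()
  inds <- c("fa", "mo", "s1", "s2")
  vcfs <- family_vcfs(chet_tab("HET", "ABSENT", "ABSENT", "HET"), inds)
  res <- apply_inheritance(vcfs, ped, "AR")
  v <- res$vcfs$s1$variants[[1]]
  expect_identical(v$model, "AR")
  expect_identical(v$chet, "G1:1:200:A:G")
  f <- tempfile(fileext = ".vcf")
  write_vcf(res$vcfs$s1, f)
  back <- read_vcf(f)
  expect_identical(back$variants[[1]]$model, "AR")
  expect_identical(back$variants[[1]]$chet, "G1:1:200:A:G")
})
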