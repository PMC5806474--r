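# Deterministic synthetic test universes: toy genome, gene map with
# isoforms, allele-frequency/domain/expression tables, and pedigree-linked
# family VCFs with one planted causal variant (or compound pair) per
# inheritance model. The same seed always yields byte-identical files.

SIM_MODELS <- c("AD", "AD_denovo", "AR_HOM", "AR_CHET", "XLD", "XLR", "mosaic")

#' Simulation specification
#'
#' Defaults describe the standard study condition used throughout the test
#' suite: three 30 kb chromosomes (one X), five two-isoform genes per
#' chromosome, 500 expected background variants per individual drawn from a
#' common-variant pool under Hardy-Weinberg, read depth 30 with +/-5 jitter,
#' and one planted causal variant (pair) consistent with the chosen model.
#'
#' @param seed Integer random seed; fixed seed implies byte-identical output.
#' @param model One of AD, AD_denovo, AR_HOM, AR_CHET, XLD, XLR, mosaic.
#' @param chromosomes Named integer vector of chromosome lengths; must
#'   include one named X.
#' @param genes_per_chrom Genes laid per chromosome.
#' @param isoforms_per_gene Isoforms per gene (>= 1; isoform 2 skips the
#'   middle exon).
#' @param n_background Expected background variant count per individual.
#' @param mean_depth,depth_jitter Read-depth model (uniform integer jitter).
#' @param mosaic_fraction Target alternate-allele fraction of the planted
#'   mosaic variant.
#' @param qual_range QUAL range for simulated records.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(seed = 1, model = "AR_CHET",
                            chromosomes = c("1" = 30000L, "2" = 30000L, "X" = 30000L),
                            genes_per_chrom = 5L, isoforms_per_gene = 2L,
                            n_background = 500L, mean_depth = 30L,
                            depth_jitter = 5L, mosaic_fraction = 0.2,
                            qual_range = c(30, 90)) {
  model <- match.arg(model, SIM_MODELS)
  stopifnot("X" %in% norm_chrom(names(chromosomes)), isoforms_per_gene >= 1,
            seed == as.integer(seed))
  structure(list(seed = as.integer(seed), model = model,
                 chromosomes = chromosomes,
                 genes_per_chrom = as.integer(genes_per_chrom),
                 isoforms_per_gene = as.integer(isoforms_per_gene),
                 n_background = as.integer(n_background),
                 mean_depth = as.integer(mean_depth),
                 depth_jitter = as.integer(depth_jitter),
                 mosaic_fraction = mosaic_fraction,
                 qual_range = qual_range),
            class = "simulation_spec")
}

# gene geometry: 3 exons of 120 bp, introns of 200 bp, CDS trimmed 30 bp
# into the terminal exons => CDS length 300 (reference isoform)
GENE_EXON_LEN <- 120L
GENE_INTRON_LEN <- 200L
GENE_UTR_LEN <- 30L
gene_span <- function() 3L * GENE_EXON_LEN + 2L * GENE_INTRON_LEN

#' Generate a synthetic test universe
#'
#' Writes a toy genome FASTA, a refGene-dialect gene map with isoforms, an
#' allele-frequency table, a protein-domain table and a tissue-expression
#' table into `dir`. The AAF table assigns common frequencies (> 5%) to most
#' background sites; a few sites are novel (absent) and the planted causal
#' site(s) for the chosen model are always omitted, so rarity filtering
#' behaves as in real case work.
#'
#' @param spec A [simulation_spec()].
#' @param dir Output directory (created if needed).
#' @return A `sim_universe` object with file paths, gene layout, the
#'   background site pool and the planted site(s).
#' @export
generate_universe <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  chroms <- names(spec$chromosomes)
  lens <- as.integer(spec$chromosomes)
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  names(seqs) <- chroms
  genome_path <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), genome_path, width = 70)

  # lay genes with promoter clearance
  span <- gene_span()
  pitch <- span + 2L * 600L
  gene_rows <- list(); g_i <- 0L
  for (ci in seq_along(chroms)) {
    for (k in seq_len(spec$genes_per_chrom)) {
      start <- 700L + (k - 1L) * pitch
      if (start + span + 700L > lens[ci]) break
      g_i <- g_i + 1L
      gene_rows[[g_i]] <- data.frame(
        gene = sprintf("G%s_%d", norm_chrom(chroms[ci]), k),
        chrom = chroms[ci],
        strand = if (g_i %% 2 == 0) "-" else "+",
        start = start, stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, gene_rows)

  map_lines <- character()
  for (i in seq_len(nrow(genes))) {
    s <- genes$start[i]
    ex_s <- c(s, s + GENE_EXON_LEN + GENE_INTRON_LEN,
              s + 2L * (GENE_EXON_LEN + GENE_INTRON_LEN))
    ex_e <- ex_s + GENE_EXON_LEN - 1L
    cds_s <- ex_s[1] + GENE_UTR_LEN
    cds_e <- ex_e[3] - GENE_UTR_LEN
    iso <- list(list(id = sprintf("NM_%04d", i), keep = 1:3))
    if (spec$isoforms_per_gene >= 2)
      iso <- c(iso, list(list(id = sprintf("NM_%04d", 1000L + i), keep = c(1L, 3L))))
    for (io in iso) {
      ks <- ex_s[io$keep]; ke <- ex_e[io$keep]
      map_lines <- c(map_lines, paste(
        0L, io$id, genes$chrom[i], genes$strand[i],
        ks[1] - 1L, ke[length(ke)],  # txStart 0-based: exon starts below are 1-based genomic
        cds_s - 1L, cds_e,
        length(ks), paste0(paste(ks - 1L, collapse = ","), ","),
        paste0(paste(ke, collapse = ","), ","),
        0L, genes$gene[i], "cmpl", "cmpl",
        paste0(paste(rep(0L, length(ks)), collapse = ","), ","),
        sep = "\t"))
    }
  }
  map_path <- file.path(dir, "genes.txt")
  writeLines(map_lines, map_path)
  transcripts <- load_gene_map(map_path)
  genome <- load_genome(genome_path)

  # background site pool: ~2x the per-individual target, 80% in gene
  # territory, carrier probability ~0.5 at the pool's mean frequency
  n_sites <- 2L * spec$n_background
  site_rows <- list()
  occupied <- new.env(parent = emptyenv())
  for (i in seq_len(n_sites)) {
    repeat {
      if (stats::runif(1) < 0.8 && nrow(genes)) {
        gi <- sample(nrow(genes), 1)
        pos <- genes$start[gi] + sample.int(span, 1) - 1L
        chrom <- genes$chrom[gi]
      } else {
        ci <- sample(length(chroms), 1)
        chrom <- chroms[ci]
        pos <- sample.int(lens[ci] - 10L, 1)
      }
      k <- paste(chrom, pos)
      if (is.null(occupied[[k]])) { assign(k, TRUE, occupied); break }
    }
    ref <- fetch_sequence(genome, chrom, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    novel <- stats::runif(1) < 0.03
    af <- if (novel) stats::runif(1, 0.0005, 0.005) else stats::runif(1, 0.05, 0.5)
    site_rows[[i]] <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                                 af = af, id = if (novel) NA_character_ else sprintf("rs%06d", i),
                                 in_table = !novel, stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, site_rows)
  sites <- sites[order(match(sites$chrom, chroms), sites$pos), ]
  rownames(sites) <- NULL

  planted <- plant_sites(spec, genes, transcripts, genome, occupied)
  aaf <- sites[sites$in_table, c("chrom", "pos", "ref", "alt", "af")]
  aaf_path <- file.path(dir, "aaf.tsv")
  utils::write.table(aaf, aaf_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  # one domain per transcript spanning the middle half of the protein
  dom_rows <- lapply(seq_along(transcripts), function(i) {
    tx <- transcripts[[i]]
    aa_len <- sum(cds_pieces(tx)[, "end"] - cds_pieces(tx)[, "start"] + 1L) %/% 3L
    data.frame(tx_id = tx$tx_id, domain = paste0("DOM_", tx$gene),
               aa_start = max(1L, aa_len %/% 4L), aa_end = max(2L, (3L * aa_len) %/% 4L),
               stringsAsFactors = FALSE)
  })
  dom_path <- file.path(dir, "domains.tsv")
  utils::write.table(do.call(rbind, dom_rows), dom_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  tissues <- c("kidney", "liver", "brain")
  expr <- matrix(round(stats::runif(nrow(genes) * length(tissues), 5, 15), 2),
                 nrow = nrow(genes), dimnames = list(genes$gene, tissues))
  expr[planted$gene, "kidney"] <- 80  # the causal gene is organ-specific
  expr_path <- file.path(dir, "expression.tsv")
  utils::write.table(cbind(gene = rownames(expr), as.data.frame(expr)),
                     expr_path, sep = "\t", quote = FALSE, row.names = FALSE)

  structure(list(dir = dir, genome_path = genome_path, gene_map_path = map_path,
                 aaf_path = aaf_path, domain_path = dom_path,
                 expression_path = expr_path, genes = genes, sites = sites,
                 planted = planted, spec = spec),
            class = "sim_universe")
}

# choose the planted causal site(s): exonic missense SNVs in the target gene
# (middle exon for the first, terminal exon for a C-HET partner), on X for
# the X-linked models
plant_sites <- function(spec, genes, transcripts, genome, occupied) {
  on_x <- norm_chrom(genes$chrom) == "X"
  pool <- if (spec$model %in% c("XLD", "XLR")) which(on_x) else which(!on_x)
  gi <- pool[length(pool) %/% 2 + 1]
  gene <- genes$gene[gi]
  tx <- transcripts[[which(vapply(transcripts, `[[`, character(1), "gene") == gene &
                             vapply(transcripts, `[[`, logical(1), "is_reference_isoform"))]]
  pick_missense <- function(cds_lo, cds_hi) {
    for (n in sample(seq(cds_lo, cds_hi))) {
      gpos <- cds_to_genomic(tx, n)
      if (!is.null(occupied[[paste(tx$chrom, gpos)]])) next
      ref <- fetch_sequence(genome, tx$chrom, gpos, gpos)
      for (alt in sample(setdiff(c("A", "C", "G", "T"), ref))) {
        fc <- classify_function(tx, "exon", gpos, ref, alt, genome)
        if (fc$mutation_type == "missense") {
          assign(paste(tx$chrom, gpos), TRUE, occupied)
          return(data.frame(chrom = tx$chrom, pos = gpos, ref = ref, alt = alt,
                            gene = gene, cdna = fc$cdna_change,
                            stringsAsFactors = FALSE))
        }
      }
    }
    stop("could not place a missense variant in ", gene)
  }
  cds_len <- 3L * GENE_EXON_LEN - 2L * GENE_UTR_LEN
  # exon 2 of the CDS spans cDNA 91..210 under the standard geometry
  first <- pick_missense(95L, 205L)
  sites <- first
  if (spec$model == "AR_CHET") {
    second <- pick_missense(10L, 85L)
    sites <- rbind(first, second)
  }
  sites$key <- paste(norm_chrom(sites$chrom), sites$pos, sites$ref, sites$alt, sep = ":")
  list(gene = gene, tx_id = tx$tx_id, sites = sites, cds_len = cds_len)
}

# family layouts per model: id, sex, affected, father, mother
model_family <- function(model) {
  trio <- function(fa_aff, mo_aff, child_sex, child_aff = "2") data.frame(
    id = c("father", "mother", "child"),
    father = c("0", "0", "father"), mother = c("0", "0", "mother"),
    sex = c("1", "2", child_sex), pheno = c(fa_aff, mo_aff, child_aff),
    stringsAsFactors = FALSE)
  quad <- function(sib1_aff, sib2_aff, sib1_sex = "2", sib2_sex = "1") data.frame(
    id = c("father", "mother", "sib1", "sib2"),
    father = c("0", "0", "father", "father"),
    mother = c("0", "0", "mother", "mother"),
    sex = c("1", "2", sib1_sex, sib2_sex),
    pheno = c("1", "1", sib1_aff, sib2_aff), stringsAsFactors = FALSE)
  switch(model,
    AD = trio("2", "1", "2"),            # affected father transmits
    AD_denovo = trio("1", "1", "2"),
    AR_HOM = quad("2", "1"),             # affected sib1, carrier sib2
    AR_CHET = quad("2", "2"),            # two affected sibs
    XLD = trio("1", "2", "2"),           # affected mother, affected daughter
    XLR = quad("2", "1", "1", "2"),      # affected son, carrier daughter
    mosaic = trio("1", "1", "2"))
}

# planted allele-count matrix (individual x site), male X hemizygous coded 2
planted_genotypes <- function(model, fam, n_sites) {
  g <- matrix(0L, nrow = nrow(fam), ncol = n_sites,
              dimnames = list(fam$id, NULL))
  set1 <- function(ind, val, site = 1L) g[ind, site] <<- val
  switch(model,
    AD = { set1("father", 1L); set1("child", 1L) },
    AD_denovo = set1("child", 1L),
    AR_HOM = { set1("father", 1L); set1("mother", 1L)
               set1("sib1", 2L); set1("sib2", 1L) },
    AR_CHET = { set1("father", 1L, 1L); set1("mother", 1L, 2L)
                set1("sib1", 1L, 1L); set1("sib1", 1L, 2L)
                set1("sib2", 1L, 1L); set1("sib2", 1L, 2L) },
    XLD = { set1("mother", 1L); set1("child", 1L) },
    XLR = { set1("mother", 1L); set1("sib1", 2L); set1("sib2", 1L) },
    mosaic = set1("child", 1L))
  g
}

#' Simulate a pedigree-linked family against a universe
#'
#' Draws founder background genotypes from the allele-frequency pool under
#' Hardy-Weinberg, transmits offspring alleles by Mendelian inheritance
#' (daughters receive the paternal X; sons are maternally hemizygous), plants
#' the model's causal variant(s), and writes one sorted single-sample VCF per
#' individual plus a 7-column PED linking individuals to their files.
#'
#' @param spec A [simulation_spec()].
#' @param universe A `sim_universe` from [generate_universe()].
#' @param dir Output directory (default: the universe directory).
#' @return A `sim_family`: `ped_path`, `vcf_paths` (named by individual),
#'   `truth` (planted keys, gene, expected per-individual zygosities).
#' @export
simulate_family <- function(spec, universe, dir = universe$dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed + 1L)
  fam <- model_family(spec$model)
  sites <- universe$sites
  n <- nrow(sites)
  is_x <- norm_chrom(sites$chrom) == "X"
  geno <- matrix(0L, nrow = nrow(fam), ncol = n, dimnames = list(fam$id, NULL))
  founders <- fam$id[fam$father == "0"]
  for (ind in founders) {
    male <- fam$sex[fam$id == ind] == "1"
    a1 <- stats::runif(n) < sites$af
    a2 <- stats::runif(n) < sites$af
    g <- as.integer(a1) + as.integer(a2)
    if (male) g[is_x] <- 2L * as.integer(a1[is_x])  # hemizygous
    geno[ind, ] <- g
  }
  draw_allele <- function(g) ifelse(g == 2L, 1L, ifelse(g == 0L, 0L,
                                                        as.integer(stats::runif(n) < 0.5)))
  for (i in which(fam$father != "0")) {
    ind <- fam$id[i]
    male <- fam$sex[i] == "1"
    fa <- draw_allele(geno[fam$father[i], ])
    ma <- draw_allele(geno[fam$mother[i], ])
    g <- fa + ma
    if (male) g[is_x] <- 2L * ma[is_x]
    else g[is_x] <- (geno[fam$father[i], is_x] %/% 2L) + ma[is_x]
    geno[ind, ] <- g
  }
  planted <- universe$planted
  pg <- planted_genotypes(spec$model, fam, nrow(planted$sites))

  truth_zyg <- lapply(fam$id, function(ind) {
    z <- ifelse(pg[ind, ] == 0L, "ABSENT", ifelse(pg[ind, ] == 1L, "HET", "HOM_ALT"))
    if (spec$model == "mosaic" && ind == "child") z[] <- "MOSAIC"
    stats::setNames(z, planted$sites$key)
  })
  names(truth_zyg) <- fam$id

  fam_name <- "FAM1"
  vcf_paths <- character(nrow(fam))
  chrom_order <- names(spec$chromosomes)
  for (i in seq_len(nrow(fam))) {
    ind <- fam$id[i]
    bg_idx <- which(geno[ind, ] > 0L)
    rows <- sites[bg_idx, c("chrom", "pos", "ref", "alt", "id"), drop = FALSE]
    rows$g <- geno[ind, bg_idx]
    rows$mosaic <- FALSE
    pl_idx <- which(pg[ind, ] > 0L)
    if (length(pl_idx)) {
      pr <- planted$sites[pl_idx, c("chrom", "pos", "ref", "alt"), drop = FALSE]
      pr$id <- NA_character_
      pr$g <- pg[ind, pl_idx]
      pr$mosaic <- spec$model == "mosaic" & ind == "child"
      rows <- rbind(rows, pr)
    }
    vcf_paths[i] <- write_sim_vcf(rows, ind, file.path(dir, sprintf("%s_%s.vcf", fam_name, ind)),
                                  spec, chrom_order)
  }
  names(vcf_paths) <- fam$id
  ped_path <- file.path(dir, paste0(fam_name, ".ped"))
  writeLines(paste(fam_name, fam$id, fam$father, fam$mother, fam$sex, fam$pheno,
                   basename(vcf_paths), sep = "\t"), ped_path)
  structure(list(ped_path = ped_path, vcf_paths = vcf_paths,
                 truth = list(model = spec$model, gene = planted$gene,
                              keys = planted$sites$key, sites = planted$sites,
                              zygosities = truth_zyg)),
            class = "sim_family")
}

write_sim_vcf <- function(rows, ind, path, spec, chrom_order) {
  n <- nrow(rows)
  depth <- spec$mean_depth +
    if (spec$depth_jitter > 0) sample(-spec$depth_jitter:spec$depth_jitter, n, replace = TRUE)
    else integer(n)
  variants <- vector("list", n)
  for (i in seq_len(n)) {
    d <- depth[i]
    if (isTRUE(rows$mosaic[i])) {
      # exact target fraction: depths computed, not sampled
      d <- spec$mean_depth
      alt_d <- as.integer(round(spec$mosaic_fraction * d))
      gt <- "0/1"
    } else if (rows$g[i] == 2L) {
      alt_d <- d; gt <- "1/1"
    } else {
      alt_d <- as.integer(round(d / 2)); gt <- "0/1"
    }
    ad <- c(d - alt_d, alt_d)
    qual <- round(stats::runif(1, spec$qual_range[1], spec$qual_range[2]), 1)
    raw <- sprintf("%s:%d,%d:%d:%d", gt, ad[1], ad[2], d, 99L)
    variants[[i]] <- list(
      chrom = rows$chrom[i], pos = as.integer(rows$pos[i]),
      id = rows$id[i], ref = rows$ref[i], alt = rows$alt[i],
      qual = qual, qual_raw = format(qual, scientific = FALSE),
      filter = "PASS", info = stats::setNames(character(), character()),
      format = c("GT", "AD", "DP", "GQ"),
      calls = stats::setNames(list(parse_call(raw, c("GT", "AD", "DP", "GQ"))), ind),
      ann = NULL, zyg = NULL)
  }
  vcf <- vcf_file(
    meta = c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s>", chrom_order),
             '##INFO=<ID=DUMMY,Number=0,Type=Flag,Description="placeholder">',
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
             '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
             '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">'),
    samples = ind, variants = variants)
  vcf <- sort_variants(vcf, chrom_order)
  write_vcf(vcf, path)
  path
}

#' Simulate a ready-to-run case directory
#'
#' Generates a universe and family for one inheritance model and writes a
#' pipeline configuration chaining core annotation, rarity filtering and the
#' model's trait-penetrance stage.
#'
#' @param model One of the seven simulation models.
#' @param dir Output directory.
#' @param seed Random seed.
#' @param n_background Background variants per individual.
#' @return A list: `universe`, `family`, `config_path`.
#' @export
simulate_case <- function(model, dir, seed = 1, n_background = 500L) {
  spec <- simulation_spec(seed = seed, model = model, n_background = n_background)
  universe <- generate_universe(spec, dir)
  family <- simulate_family(spec, universe, dir)
  stage <- if (model == "mosaic")
    list(name = "mosaic", params = list(min_af = 0.10, max_af = 0.35))
  else
    list(name = "inheritance",
         params = list(model = switch(model, AD_denovo = "AD_denovo",
                                      AR_HOM = "AR", AR_CHET = "AR",
                                      AD = "AD", XLD = "XLD", XLR = "XLR")))
  # paths are written relative to the config file so the directory is movable
  config <- list(
    run_id = paste0("sim_", tolower(model)),
    output_dir = "out",
    pedigree = basename(family$ped_path),
    genome = basename(universe$genome_path),
    gene_map = basename(universe$gene_map_path),
    aaf_table = basename(universe$aaf_path),
    domain_table = basename(universe$domain_path),
    expression_table = basename(universe$expression_path),
    stages = list(
      list(name = "add_genes", params = list(promoter_bp = 500, splice_bp = 5)),
      list(name = "add_function", params = list()),
      list(name = "add_zygosity", params = list(lo = 0.15, hi = 0.85)),
      list(name = "filter_aaf", params = list(max_af = 0.01)),
      stage))
  config_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, config_path)
  list(universe = universe, family = family, config_path = config_path)
}
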