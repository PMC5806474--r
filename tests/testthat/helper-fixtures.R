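# Shared fixture builders and independent oracles. Oracles here re-derive
# expectations from first principles (per-base scans, direct predicate
# evaluation, plain-loop rule application) and never call the code paths
# they check.

mk_variant <- function(chrom = "1", pos = 100L, ref = "A", alt = "G",
                       id = NA_character_, qual = 50, filter = "PASS",
                       gt = "0/1", ad = NULL, dp = NULL, sample = "S1") {
  fields <- c("GT")
  parts <- gt
  if (!is.null(ad)) { fields <- c(fields, "AD"); parts <- c(parts, paste(ad, collapse = ",")) }
  if (!is.null(dp)) { fields <- c(fields, "DP"); parts <- c(parts, dp) }
  raw <- paste(parts, collapse = ":")
  qual_raw <- if (is.na(qual)) "." else format(qual, scientific = FALSE)
  list(chrom = chrom, pos = as.integer(pos), id = id, ref = ref,
       alt = as.character(alt),
       qual = if (is.na(qual)) NA_real_ else as.numeric(qual),
       qual_raw = qual_raw, filter = filter,
       info = stats::setNames(character(), character()),
       format = fields,
       calls = stats::setNames(list(varseg:::parse_call(raw, fields)), sample),
       ann = NULL, zyg = NULL)
}

mk_vcf <- function(variants, sample = "S1",
                   meta = c("##fileformat=VCFv4.2",
                            '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')) {
  vcf_file(meta = meta, samples = sample, variants = variants)
}

# write a refGene-dialect row (bin-less): 1-based inclusive inputs
refgene_row <- function(tx_id, chrom, strand, exons, cds_start, cds_end,
                        gene, coding = TRUE) {
  ex_s <- vapply(exons, `[`, numeric(1), 1)
  ex_e <- vapply(exons, `[`, numeric(1), 2)
  raw_cds_s <- if (coding) cds_start - 1 else cds_end
  raw_cds_e <- cds_end
  paste(tx_id, chrom, strand, ex_s[1] - 1, ex_e[length(ex_e)],
        raw_cds_s, raw_cds_e, length(exons),
        paste0(paste(ex_s - 1, collapse = ","), ","),
        paste0(paste(ex_e, collapse = ","), ","),
        0, gene, sep = "\t")
}

write_gene_map <- function(rows) {
  f <- tempfile(fileext = ".txt")
  writeLines(rows, f)
  f
}

# random transcript rows on one chromosome for oracle testing
random_gene_map <- function(n_tx = 3, chrom_len = 2000, chrom = "1") {
  rows <- character(n_tx)
  for (i in seq_len(n_tx)) {
    n_ex <- sample(1:3, 1)
    start <- sample(300:(chrom_len - 900), 1)
    ex <- list(); cur <- start
    for (e in seq_len(n_ex)) {
      w <- sample(30:120, 1)
      ex[[e]] <- c(cur, cur + w - 1)
      cur <- cur + w + sample(12:200, 1)
    }
    span <- c(ex[[1]][1], ex[[n_ex]][2])
    coding <- stats::runif(1) < 0.8
    if (coding) {
      cds_s <- ex[[1]][1] + sample(0:20, 1)
      cds_e <- ex[[n_ex]][2] - sample(0:20, 1)
    } else { cds_s <- NA; cds_e <- span[2] }
    rows[i] <- refgene_row(sprintf("NM_%03d", i), chrom,
                           sample(c("+", "-"), 1), ex,
                           if (coding) cds_s else NA, cds_e,
                           sprintf("GENE%d", i), coding = coding)
  }
  rows
}

# independent per-base region classifier: direct rules per transcript,
# no interval carving, no overlap index
oracle_region_labels <- function(tx, p, params) {
  ex <- tx$exons
  sw <- params$splice_bp; pbp <- params$promoter_bp
  plus <- tx$strand == "+"
  lab <- NULL
  if (any(p >= ex[, 1] & p <= ex[, 2])) {
    if (!tx$coding) lab <- "exon"
    else if (p >= tx$cds_start && p <= tx$cds_end) lab <- "exon"
    else if (plus == (p < tx$cds_start)) lab <- "utr5"
    else lab <- "utr3"
  } else if (p >= tx$tx_start && p <= tx$tx_end) {
    prev_end <- max(ex[ex[, 2] < p, 2])
    next_start <- min(ex[ex[, 1] > p, 1])
    len <- next_start - prev_end - 1
    lw <- min(sw, len); rw <- min(sw, len - lw)
    dl <- p - prev_end; dr <- next_start - p
    lab <- if (dl <= lw) { if (plus) "splice_donor" else "splice_acceptor" }
    else if (dr <= rw) { if (plus) "splice_acceptor" else "splice_donor" }
    else "intron"
  } else if (p < tx$tx_start && p >= tx$tx_start - pbp) {
    lab <- if (plus) "promoter_up" else "promoter_down"
  } else if (p > tx$tx_end && p <= tx$tx_end + pbp) {
    lab <- if (plus) "promoter_down" else "promoter_up"
  }
  intersect(lab, params$enabled_regions)
}

write_fasta <- function(seqs) {
  f <- tempfile(fileext = ".fa")
  con <- file(f, "w")
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    writeLines(gsub("(.{70})", "\\1\n", seqs[[nm]]), con)
  }
  close(con)
  f
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# minimal pedigree data frame with the class the package produces
mk_ped <- function(ids, fathers, mothers, sexes, affecteds, family = "F1") {
  ped <- data.frame(family_id = family, individual_id = ids,
                    father_id = fathers, mother_id = mothers,
                    sex = sexes, affected = affecteds,
                    vcf_path = NA_character_, stringsAsFactors = FALSE)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

trio_ped <- function(father_aff = "unaffected", mother_aff = "unaffected",
                     child_aff = "affected", child_sex = "female") {
  mk_ped(c("fa", "mo", "ch"),
         c(NA, NA, "fa"), c(NA, NA, "mo"),
         c("male", "female", child_sex),
         c(father_aff, mother_aff, child_aff))
}

# one-variant single-sample VCF with a forced zygosity, for view building
zyg_vcf <- function(ind, zyg, chrom = "1", pos = 100L, ref = "A", alt = "G",
                    gene = NULL) {
  gt <- switch(zyg, HOM_REF = "0/0", HET = "0/1", HOM_ALT = "1/1")
  v <- mk_variant(chrom = chrom, pos = pos, ref = ref, alt = alt,
                  gt = gt, sample = ind)
  if (!is.null(gene))
    v$ann <- data.frame(alt = alt, gene = gene, tx_id = paste0("TX_", gene),
                        region = "exon", cdna = NA_character_,
                        mut = NA_character_, aa = NA_character_,
                        iso = NA_character_, refseq = NA_character_,
                        domain = NA_character_, stringsAsFactors = FALSE)
  mk_vcf(list(v), sample = ind)
}

# multi-variant per-individual VCFs from a zygosity table:
# tab: data.frame(chrom, pos, ref, alt, gene, <one column per individual>)
family_vcfs <- function(tab, individuals) {
  out <- lapply(individuals, function(ind) {
    keep <- tab[[ind]] != "ABSENT"
    vars <- lapply(which(keep), function(i) {
      v <- mk_variant(chrom = tab$chrom[i], pos = tab$pos[i], ref = tab$ref[i],
                      alt = tab$alt[i],
                      gt = switch(tab[[ind]][i], HOM_REF = "0/0",
                                  HET = "0/1", HOM_ALT = "1/1"),
                      sample = ind)
      if (!is.null(tab$gene) && !is.na(tab$gene[i]))
        v$ann <- data.frame(alt = v$alt, gene = tab$gene[i],
                            tx_id = paste0("TX_", tab$gene[i]), region = "exon",
                            cdna = NA_character_, mut = NA_character_,
                            aa = NA_character_, iso = NA_character_,
                            refseq = NA_character_, domain = NA_character_,
                            stringsAsFactors = FALSE)
      v
    })
    mk_vcf(vars, sample = ind)
  })
  names(out) <- individuals
  out
}

# zygosity from a raw VCF sample field, derived straight from AD (falling
# back to GT), as an independent route for the inheritance enumerator
raw_zygosity <- function(raw, lo = 0.15, hi = 0.85) {
  parts <- strsplit(raw, ":", fixed = TRUE)[[1]]
  ad <- suppressWarnings(as.integer(strsplit(parts[2], ",")[[1]]))
  if (length(ad) >= 2 && !anyNA(ad) && sum(ad) > 0) {
    f <- sum(ad[-1]) / sum(ad)
    if (f < lo) return("HOM_REF")
    if (f <= hi) return("HET")
    return("HOM_ALT")
  }
  gt <- strsplit(parts[1], "[/|]")[[1]]
  if (all(gt == "0")) "HOM_REF" else if (all(gt != "0")) "HOM_ALT" else "HET"
}

# read a VCF body with base R only: list of (chrom, pos, ref, alt, call raw,
# VS_GENE genes) — the enumerator's own I/O path
scan_vcf_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body))
    return(data.frame(key = character(), raw = character(), genes = character()))
  cols <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  genes <- vapply(cols[, 8], function(info) {
    m <- regmatches(info, regexpr("VS_GENE=[^;]+", info))
    if (!length(m)) "" else sub("VS_GENE=", "", m)
  }, character(1), USE.NAMES = FALSE)
  data.frame(
    key = paste(sub("^chr", "", cols[, 1]), cols[, 2], cols[, 4], cols[, 5], sep = ":"),
    raw = cols[, ncol(cols)], genes = genes, stringsAsFactors = FALSE)
}

# brute-force trait-penetrance enumerator: plain loops over a zygosity
# matrix, re-stating the model rules independently of the package filters.
# zmat: keys x individuals ("MISSING" when uncalled); ped: pedigree df;
# genes: named list key -> gene symbols; chromx: named logical (key on X)
enumerate_inheritance <- function(model, zmat, ped, genes, chromx) {
  keys <- rownames(zmat)
  aff <- ped$individual_id[ped$affected == "affected"]
  aff <- intersect(aff, colnames(zmat))
  unaff <- intersect(ped$individual_id[ped$affected == "unaffected"], colnames(zmat))
  carrier <- function(z) z %in% c("HET", "HOM_ALT")
  male <- function(ind) ped$sex[ped$individual_id == ind] == "male"
  par_of <- function(ind) {
    r <- ped[ped$individual_id == ind, ]
    c(father = r$father_id, mother = r$mother_id)
  }
  z <- function(k, ind) if (ind %in% colnames(zmat)) zmat[k, ind] else "MISSING"
  known <- function(k, ind) !is.na(ind) && z(k, ind) != "MISSING"
  x_keys <- keys[chromx[keys]]
  a_keys <- setdiff(keys, x_keys)

  dominant <- function(cand, de_novo) {
    Filter(function(k) {
      for (a in aff) if (!carrier(z(k, a))) return(FALSE)
      for (u in unaff) if (carrier(z(k, u))) return(FALSE)
      if (!de_novo) {
        for (a in aff) {
          ps <- par_of(a); ps <- ps[!is.na(ps)]
          ps <- ps[vapply(ps, function(p) known(k, p), logical(1))]
          if (!length(ps)) next
          ok <- FALSE
          for (p in ps)
            if (ped$affected[ped$individual_id == p] == "affected" &&
                carrier(z(k, p))) ok <- TRUE
          if (!ok) return(FALSE)
        }
      }
      TRUE
    }, cand)
  }

  recessive <- function(cand, x_linked) {
    homreq <- function(k, ind) {
      if (x_linked && male(ind)) carrier(z(k, ind)) else z(k, ind) == "HOM_ALT"
    }
    hom <- Filter(function(k) {
      for (a in aff) if (!homreq(k, a)) return(FALSE)
      for (u in unaff) if (homreq(k, u)) return(FALSE)
      for (a in aff) {
        ps <- par_of(a)
        if (x_linked && male(a)) {
          m <- ps[["mother"]]
          if (known(k, m) && !carrier(z(k, m))) return(FALSE)
          next
        }
        for (p in ps) {
          if (!known(k, p)) next
          if (x_linked && male(p)) {
            if (!carrier(z(k, p))) return(FALSE)
          } else if (z(k, p) != "HET") return(FALSE)
        }
      }
      TRUE
    }, cand)
    chet_aff <- if (x_linked) Filter(function(a) !male(a), aff) else aff
    chet <- character()
    if (length(chet_aff)) {
      gene_of <- list()
      for (k in cand) for (g in genes[[k]])
        gene_of[[g]] <- c(gene_of[[g]], k)
      for (g in names(gene_of)) {
        cs <- unique(gene_of[[g]])
        cs <- Filter(function(k) {
          for (a in chet_aff) if (z(k, a) != "HET") return(FALSE)
          if (x_linked)
            for (a in aff) if (male(a) && !carrier(z(k, a))) return(FALSE)
          for (u in unaff) if (homreq(k, u)) return(FALSE)
          TRUE
        }, cs)
        if (length(cs) < 2) next
        ps <- par_of(chet_aff[1])
        f <- ps[["father"]]; m <- ps[["mother"]]
        f_known <- !is.na(f) && any(vapply(cs, function(k) known(k, f), logical(1)))
        m_known <- !is.na(m) && any(vapply(cs, function(k) known(k, m), logical(1)))
        if (!is.na(f) && !is.na(m) && f_known && m_known) {
          pat <- Filter(function(k) carrier(z(k, f)) && !carrier(z(k, m)), cs)
          mat <- Filter(function(k) carrier(z(k, m)) && !carrier(z(k, f)), cs)
          if (length(pat) && length(mat)) chet <- c(chet, pat, mat)
        } else chet <- c(chet, cs)
      }
    }
    unique(c(unlist(hom), chet))
  }

  switch(model,
    AD = unlist(dominant(a_keys, FALSE)),
    AD_denovo = unlist(dominant(a_keys, TRUE)),
    AR = recessive(a_keys, FALSE),
    XLD = unlist(dominant(x_keys, FALSE)),
    XLR = recessive(x_keys, TRUE)) -> res
  if (is.null(res)) character() else res
}

# a two-chromosome toy genome whose first transcript is plus-strand and
# whose second (on chr2, minus strand) has the same cDNA sequence
codon_fixture <- function() {
  codons <- apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                              c("T", "C", "A", "G"))[, 3:1], 1, paste, collapse = "")
  cds <- paste(codons, collapse = "")  # 192 bases, all 64 codons
  utr <- 30L
  chr1 <- paste0(random_dna(utr), cds, random_dna(utr))
  chr2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(chr1)))
  genome_path <- write_fasta(list(`1` = chr1, `2` = chr2))
  L <- nchar(chr1)
  rows <- c(
    refgene_row("NM_P", "1", "+", list(c(1, L)), utr + 1, utr + 192, "GPLUS"),
    refgene_row("NM_M", "2", "-", list(c(1, L)), utr + 1, utr + 192, "GMINUS"))
  txs <- load_gene_map(write_gene_map(rows))
  list(genome = load_genome(genome_path), txs = txs, codons = codons, utr = utr,
       chr1 = chr1, chr2 = chr2)
}

# the classification decision rules restated over an independent translation
# route (seqinr), for the exhaustive codon enumeration
oracle_type <- function(codon_before, codon_after) {
  tr <- function(s) toupper(seqinr::translate(seqinr::s2c(s)))
  a1 <- tr(codon_before); a2 <- tr(codon_after)
  if (a1 == a2) "synonymous"
  else if (a2 == "*") "nonsense"
  else if (a1 == "*") "stoploss"
  else "missense"
}

random_variant_set <- function(n = 1000, seed = 3) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    v <- mk_variant(chrom = sample(c("1", "2", "X"), 1), pos = sample(50000L, 1),
                    ref = sample(c("A", "C", "G", "T"), 1),
                    alt = sample(c("A", "C", "G", "T"), 1),
                    id = if (runif(1) < 0.4) sprintf("rs%d", i) else NA_character_,
                    qual = if (runif(1) < 0.1) NA else round(runif(1, 0, 60), 1),
                    ad = sample(0:25, 2), dp = sample(0:40, 1))
    if (runif(1) < 0.8) {
      n_ann <- sample(1:2, 1)
      v$ann <- data.frame(
        alt = rep(v$alt[1], n_ann), gene = sample(sprintf("G%d", 1:20), n_ann),
        tx_id = sprintf("NM_%d", sample(100, n_ann)),
        region = sample(c("exon", "intron", "splice_donor", "promoter_up"),
                        n_ann, replace = TRUE),
        cdna = NA_character_,
        mut = sample(c("missense", "synonymous", "nonsense", "noncoding"),
                     n_ann, replace = TRUE),
        aa = NA_character_, iso = NA_character_, refseq = NA_character_,
        domain = NA_character_, stringsAsFactors = FALSE)
    }
    v
  })
}
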