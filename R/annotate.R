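# Core annotation: the three mandatory annotators that prime variants for
# every downstream filter — gene context, codon-level functional consequence,
# and base-count zygosity.

#' Load an indexed reference genome
#'
#' Reads a FASTA file into memory via Biostrings for random access. Sequence
#' names are truncated at the first whitespace and normalised for the "chr"
#' prefix.
#'
#' @param path FASTA path.
#' @return A `genome_sequence` object.
#' @export
load_genome <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  names(set) <- norm_chrom(sub("\\s.*$", "", names(set)))
  # plain character storage: random access is a substr(), far cheaper than
  # repeated S4 subsetting in the per-codon lookups
  seqs <- stats::setNames(toupper(as.character(set)), names(set))
  structure(list(seqs = seqs), class = "genome_sequence")
}

#' Fetch genome sequence
#'
#' @param genome A `genome_sequence`.
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive bounds.
#' @return Uppercase sequence string of length `end - start + 1`.
#' @export
fetch_sequence <- function(genome, chrom, start, end) {
  chrom <- norm_chrom(chrom)
  if (!chrom %in% names(genome$seqs))
    stop("chromosome not in genome FASTA: ", chrom)
  if (start < 1 || end > nchar(genome$seqs[[chrom]]) || start > end)
    stop(sprintf("sequence fetch out of bounds: %s:%d-%d", chrom, start, end))
  substr(genome$seqs[[chrom]], start, end)
}

complement_base <- function(x) chartr("ACGTN", "TGCAN", x)

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", "*" = "Ter")

translate_codon <- function(codon) {
  if (grepl("N", codon)) return(NA_character_)
  unname(Biostrings::GENETIC_CODE[codon])
}

# genomic position of CDS base n (1-based in transcription direction)
cds_to_genomic <- function(tx, n) {
  pieces <- cds_pieces(tx)
  i <- which(n > pieces[, "before"] &
             n <= pieces[, "before"] + pieces[, "end"] - pieces[, "start"] + 1L)[1]
  off <- n - pieces[i, "before"] - 1L
  if (tx$strand == "+") pieces[i, "start"] + off else pieces[i, "end"] - off
}

#' Annotate variants with gene context
#'
#' Attaches one in-line annotation per overlapping (transcript, region) pair
#' and per alternate allele; variants overlapping nothing are wholly
#' intergenic and are discarded unless `keep_intergenic`. Any annotations
#' from a previous run are replaced, so the operation is idempotent.
#'
#' @param vcf A sorted `vcf_file`.
#' @param map A `region_map`.
#' @param keep_intergenic Keep variants with no gene context? Default FALSE.
#' @return The annotated (and possibly reduced) `vcf_file`.
#' @export
annotate_genes <- function(vcf, map, keep_intergenic = FALSE) {
  chroms <- vapply(vcf$variants, function(v) norm_chrom(v$chrom), character(1))
  pos <- vapply(vcf$variants, function(v) v$pos, integer(1))
  blocks <- rle(chroms)$values
  if (anyDuplicated(blocks) ||
      any(vapply(split(seq_along(pos), chroms), function(ix) is.unsorted(pos[ix]), logical(1))))
    stop("annotate_genes requires position-sorted input; run sort_variants() first")
  p_bp <- map$params$promoter_bp
  out <- vcf$variants
  for (ch in unique(chroms)) {
    ix <- which(chroms == ch)
    hits <- region_hits(map, ch, pos[ix])
    hit_by_var <- split(seq_len(nrow(hits)), hits$pos_index)
    for (j in seq_along(ix)) {
      vi <- ix[j]
      v <- out[[vi]]
      rows <- hit_by_var[[as.character(j)]]
      if (is.null(rows) || !length(v$alt)) { out[[vi]]$ann <- empty_ann(); next }
      tx_idx <- hits$tx[rows]
      regions <- hits$region[rows]
      labels <- vapply(tx_idx, function(t)
        cdna_position(map$transcripts[[t]], v$pos, p_bp), character(1))
      n_hit <- length(rows); n_alt <- length(v$alt)
      ann <- data.frame(
        alt = rep(v$alt, each = n_hit),
        gene = rep(vapply(tx_idx, function(t) map$transcripts[[t]]$gene, character(1)), n_alt),
        tx_id = rep(vapply(tx_idx, function(t) map$transcripts[[t]]$tx_id, character(1)), n_alt),
        region = rep(regions, n_alt),
        cdna = rep(labels, n_alt),
        mut = NA_character_, aa = NA_character_, iso = NA_character_,
        refseq = NA_character_, domain = NA_character_,
        stringsAsFactors = FALSE)
      out[[vi]]$ann <- ann
    }
  }
  vcf$variants <- out
  if (!keep_intergenic)
    vcf <- subset_variants(vcf, vapply(vcf$variants, function(v) n_ann(v) > 0, logical(1)))
  vcf
}

#' Classify the functional consequence of one variant on one transcript
#'
#' For an exonic SNV the reference codon is reconstructed from CDS
#' coordinates (reverse-complemented for minus-strand transcripts), the
#' alternate base substituted and both codons translated under the standard
#' nuclear code: identical amino acid gives `synonymous`, an alternate stop
#' gives `nonsense`, a lost reference stop `stoploss`, anything else
#' `missense`. Exonic indels are `frameshift` when the length change is not a
#' multiple of 3 and `inframe_indel` otherwise. Non-exonic contexts are
#' `noncoding` but keep their region label so splice/promoter hits remain
#' selectable downstream.
#'
#' @param tx Transcript record.
#' @param region Region class of the annotation.
#' @param pos,ref,alt Variant coordinates and alleles (plus-strand).
#' @param genome A `genome_sequence`.
#' @param promoter_bp Flank reach used for cDNA labelling.
#' @return A list: `mutation_type`, `cdna_change`, `protein_change`,
#'   `codon_before`, `codon_after`, `flagged` (TRUE when the VCF ref
#'   disagrees with the genome FASTA).
#' @export
classify_function <- function(tx, region, pos, ref, alt, genome, promoter_bp = 500) {
  flagged <- FALSE
  is_snv <- nchar(ref) == 1 && nchar(alt) == 1
  if (is_snv) {
    genome_base <- fetch_sequence(genome, tx$chrom, pos, pos)
    if (genome_base != ref) {
      warning(sprintf("reference mismatch at %s:%d (VCF %s, FASTA %s); annotation flagged",
                      tx$chrom, pos, ref, genome_base))
      flagged <- TRUE
    }
  }
  label <- cdna_position(tx, pos, promoter_bp)
  minus <- tx$strand == "-"
  if (region != "exon" || !tx$coding) {
    change <- if (is_snv) {
      r <- if (minus) complement_base(ref) else ref
      a <- if (minus) complement_base(alt) else alt
      paste0(label, r, ">", a)
    } else indel_label(label, ref, alt, minus)
    return(list(mutation_type = "noncoding", cdna_change = change,
                protein_change = NA_character_, codon_before = NA_character_,
                codon_after = NA_character_, flagged = flagged))
  }
  co <- cdna_coord(tx, pos)
  if (co$kind != "cds")
    stop(sprintf("internal consistency error: exon-labelled annotation at %s:%d maps outside the CDS of %s",
                 tx$chrom, pos, tx$tx_id))
  if (!is_snv) {
    delta <- nchar(alt) - nchar(ref)
    type <- if (delta %% 3 != 0) "frameshift" else "inframe_indel"
    return(list(mutation_type = type,
                cdna_change = indel_label(label, ref, alt, minus),
                protein_change = NA_character_, codon_before = NA_character_,
                codon_after = NA_character_, flagged = flagged))
  }
  n <- co$n
  codon_idx <- (n - 1L) %/% 3L
  within <- (n - 1L) %% 3L + 1L
  cds_ns <- codon_idx * 3L + 1:3
  bases <- vapply(cds_ns, function(m) {
    gpos <- cds_to_genomic(tx, m)
    b <- fetch_sequence(genome, tx$chrom, gpos, gpos)
    if (minus) complement_base(b) else b
  }, character(1))
  codon_before <- paste(bases, collapse = "")
  ref_cdna <- if (minus) complement_base(ref) else ref
  alt_cdna <- if (minus) complement_base(alt) else alt
  bases[within] <- alt_cdna
  codon_after <- paste(bases, collapse = "")
  aa1 <- translate_codon(codon_before)
  aa2 <- translate_codon(codon_after)
  type <- if (is.na(aa1) || is.na(aa2)) "missense"
  else if (aa1 == aa2) "synonymous"
  else if (aa2 == "*") "nonsense"
  else if (aa1 == "*") "stoploss"
  else "missense"
  protein <- if (is.na(aa1) || is.na(aa2)) NA_character_
  else sprintf("p.%s%d%s", AA3[[aa1]], codon_idx + 1L, AA3[[aa2]])
  list(mutation_type = type,
       cdna_change = sprintf("%s%s>%s", label, ref_cdna, alt_cdna),
       protein_change = protein,
       codon_before = codon_before, codon_after = codon_after,
       flagged = flagged)
}

# simplified indel label: c.<pos>del<seq> / ins<seq> / delins<seq> (no
# 3'-shifting HGVS normalisation)
indel_label <- function(label, ref, alt, minus) {
  strand_seq <- function(s) {
    if (!minus) return(s)
    paste(rev(strsplit(complement_base(s), "")[[1]]), collapse = "")
  }
  if (nchar(ref) > 1 && nchar(alt) == 1 && substr(ref, 1, 1) == alt)
    paste0(label, "del", strand_seq(substr(ref, 2, nchar(ref))))
  else if (nchar(alt) > 1 && nchar(ref) == 1 && substr(alt, 1, 1) == ref)
    paste0(label, "ins", strand_seq(substr(alt, 2, nchar(alt))))
  else
    paste0(label, "delins", strand_seq(alt))
}

#' Annotate functional consequences on all in-line gene contexts
#'
#' Applies [classify_function()] to every (variant, transcript annotation,
#' alternate allele) triple, filling the `mut`, `cdna` and `aa` columns of
#' the in-line annotation arrays.
#'
#' @param vcf An annotated `vcf_file` (after [annotate_genes()]).
#' @param map The `region_map` used for gene annotation.
#' @param genome A `genome_sequence`.
#' @return The `vcf_file` with functional annotations.
#' @export
annotate_functions <- function(vcf, map, genome) {
  tx_lookup <- stats::setNames(seq_along(map$transcripts),
                               vapply(map$transcripts, `[[`, character(1), "tx_id"))
  p_bp <- map$params$promoter_bp
  vcf$variants <- lapply(vcf$variants, function(v) {
    if (n_ann(v) == 0) return(v)
    for (i in seq_len(nrow(v$ann))) {
      tx <- map$transcripts[[tx_lookup[[v$ann$tx_id[i]]]]]
      fc <- classify_function(tx, v$ann$region[i], v$pos, v$ref, v$ann$alt[i],
                              genome, promoter_bp = p_bp)
      v$ann$mut[i] <- fc$mutation_type
      v$ann$cdna[i] <- fc$cdna_change
      v$ann$aa[i] <- fc$protein_change
    }
    v
  })
  vcf
}

#' Assign zygosity from nucleotide base counts
#'
#' Recomputes each sample's zygosity from per-allele read counts rather than
#' trusting the caller's GT, addressing confidence issues in pre-processed
#' genotypes: with alternate-allele fraction `f = alt / (ref + alt)`,
#' `f < lo` is HOM_REF, `lo <= f <= hi` is HET and `f > hi` is HOM_ALT.
#' Samples without usable counts fall back to the GT field; without GT they
#' are MISSING. Every sample of every variant receives exactly one value.
#'
#' @param vcf A `vcf_file`.
#' @param lo,hi Alternate-allele fraction thresholds (defaults 0.15 / 0.85,
#'   keeping the 50% heterozygous band wide of the 10-35% mosaic window).
#' @return The `vcf_file` with per-sample zygosity stored in-line.
#' @export
assign_zygosity <- function(vcf, lo = 0.15, hi = 0.85) {
  vcf$variants <- lapply(vcf$variants, function(v) {
    z <- vapply(vcf$samples, function(s) {
      cl <- v$calls[[s]]
      if (is.null(cl)) return("MISSING")
      ad <- cl$allele_depths
      if (!is.null(ad) && !anyNA(ad) && length(ad) >= 2 && sum(ad) > 0) {
        f <- sum(ad[-1]) / sum(ad)
        if (f < lo) return("HOM_REF")
        if (f <= hi) return("HET")
        return("HOM_ALT")
      }
      g <- cl$gt_alleles
      if (is.null(g) || !length(g) || anyNA(g)) return("MISSING")
      if (all(g == 0)) "HOM_REF" else if (all(g > 0)) "HOM_ALT" else "HET"
    }, character(1))
    v$zyg <- z
    v
  })
  vcf
}

#' Zygosity of one sample at one variant
#'
#' Reads the stored base-count zygosity if present, otherwise falls back to
#' the GT field.
#'
#' @param v A variant record.
#' @param sample Sample name.
#' @return One of "HOM_REF", "HET", "HOM_ALT", "MISSING".
#' @export
zygosity_of <- function(v, sample) {
  if (!is.null(v$zyg) && sample %in% names(v$zyg)) return(unname(v$zyg[[sample]]))
  cl <- v$calls[[sample]]
  if (is.null(cl)) return("MISSING")
  g <- cl$gt_alleles
  if (is.null(g) || !length(g) || anyNA(g)) return("MISSING")
  if (all(g == 0)) "HOM_REF" else if (all(g > 0)) "HOM_ALT" else "HET"
}
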