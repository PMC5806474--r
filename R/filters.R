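# The chainable variant filters. Every filter is a contraction (output is a
# subset of input, annotations untouched) and idempotent; single-file
# predicate filters commute with one another.

#' Read a BED-dialect region file
#'
#' BED intervals are 0-based half-open on disk; they are converted to the
#' package-internal 1-based inclusive convention at load.
#'
#' @param path BED path.
#' @return A data frame with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    chrom = vapply(rows, `[`, character(1), 1),
    start = vapply(rows, function(r) as.integer(r[2]) + 1L, integer(1)),
    end = vapply(rows, function(r) as.integer(r[3]), integer(1)),
    stringsAsFactors = FALSE)
}

#' Filter by physical location
#'
#' @param vcf A `vcf_file`.
#' @param regions Data frame with `chrom`, `start`, `end` (1-based
#'   inclusive), e.g. from [read_bed()].
#' @param mode `"keep"` retains variants overlapping any interval;
#'   `"discard"` is the complement.
#' @return The filtered `vcf_file`.
#' @export
filter_physical_location <- function(vcf, regions, mode = c("keep", "discard")) {
  mode <- match.arg(mode)
  if (!nrow(regions)) stop("filter_physical_location needs a non-empty region set")
  rchrom <- norm_chrom(regions$chrom)
  hit <- vapply(vcf$variants, function(v) {
    span <- v$pos + nchar(v$ref) - 1L
    any(rchrom == norm_chrom(v$chrom) & regions$start <= span & regions$end >= v$pos)
  }, logical(1))
  subset_variants(vcf, if (mode == "keep") hit else !hit)
}

#' Filter by read depth
#'
#' @param vcf A `vcf_file`.
#' @param min_dp Minimum total read depth (kept when `depth >= min_dp`).
#' @param scope `"any_sample"` keeps a variant when any sample meets the
#'   threshold; `"all_samples"` requires all. Missing depth fails.
#' @return The filtered `vcf_file`.
#' @export
filter_read_depth <- function(vcf, min_dp, scope = c("any_sample", "all_samples")) {
  scope <- match.arg(scope)
  stopifnot(min_dp >= 0)
  keep <- vapply(vcf$variants, function(v) {
    ok <- vapply(vcf$samples, function(s) {
      cl <- v$calls[[s]]
      dp <- if (is.null(cl)) NA_integer_ else cl$depth
      if (is.na(dp) && !is.null(cl) && !is.null(cl$allele_depths) && !anyNA(cl$allele_depths))
        dp <- sum(cl$allele_depths)
      !is.na(dp) && dp >= min_dp
    }, logical(1))
    if (!length(ok)) return(FALSE)
    if (scope == "any_sample") any(ok) else all(ok)
  }, logical(1))
  subset_variants(vcf, keep)
}

#' Filter by call quality
#'
#' Keeps variants with `QUAL` strictly greater than the threshold (the
#' conventional "> 20" usage); missing QUAL fails.
#'
#' @param vcf A `vcf_file`.
#' @param min_qual Quality threshold (strict).
#' @return The filtered `vcf_file`.
#' @export
filter_call_quality <- function(vcf, min_qual) {
  stopifnot(min_qual >= 0)
  keep <- vapply(vcf$variants, function(v) !is.na(v$qual) && v$qual > min_qual,
                 logical(1))
  subset_variants(vcf, keep)
}

#' Filter by mutation type or region class
#'
#' A variant survives when ANY of its in-line transcript annotations matches
#' `keep_types` (by mutation type or by region class); non-matching
#' annotations on surviving variants are retained — the filter acts at the
#' variant level but matches at the annotation level.
#'
#' @param vcf A functionally annotated `vcf_file`.
#' @param keep_types Character vector of mutation types
#'   (synonymous/missense/nonsense/stoploss/frameshift/inframe_indel/
#'   noncoding) and/or region classes (exon/splice_donor/...).
#' @return The filtered `vcf_file`.
#' @export
filter_mutation_type <- function(vcf, keep_types) {
  annotated <- vapply(vcf$variants, function(v) n_ann(v) > 0 && !all(is.na(v$ann$mut)),
                      logical(1))
  if (length(vcf$variants) && !any(annotated))
    stop("variants carry no functional annotations; run annotate_genes()/annotate_functions() first")
  keep <- vapply(vcf$variants, function(v) {
    if (n_ann(v) == 0) return(FALSE)
    any(v$ann$mut %in% keep_types | v$ann$region %in% keep_types)
  }, logical(1))
  subset_variants(vcf, keep)
}

#' Load a population allele-frequency table
#'
#' Tab-separated columns chrom, pos, ref, alt, af. Rows are loaded lazily one
#' chromosome at a time and cached, so only the chromosomes actually queried
#' pay the load cost.
#'
#' @param path TSV path.
#' @return An `aaf_table` object.
#' @export
load_aaf_table <- function(path) {
  structure(list(path = path, cache = new.env(parent = emptyenv())),
            class = "aaf_table")
}

aaf_chrom_env <- function(table, chrom) {
  chrom <- norm_chrom(chrom)
  if (!is.null(table$cache[[chrom]])) return(table$cache[[chrom]])
  df <- utils::read.table(table$path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "pos", "ref", "alt", "af"),
                          colClasses = c("character", "integer", "character",
                                         "character", "numeric"))
  df <- df[norm_chrom(df$chrom) == chrom, , drop = FALSE]
  e <- new.env(parent = emptyenv())
  if (nrow(df)) {
    keys <- paste(df$pos, df$ref, df$alt, sep = ":")
    for (i in seq_len(nrow(df))) assign(keys[i], df$af[i], envir = e)
  }
  table$cache[[chrom]] <- e
  e
}

#' Look up a population allele frequency
#'
#' @param table An `aaf_table`.
#' @param chrom,pos,ref,alt Variant coordinates.
#' @return Frequency in `[0, 1]`, or `NA` when the variant is absent.
#' @export
aaf_lookup <- function(table, chrom, pos, ref, alt) {
  e <- aaf_chrom_env(table, chrom)
  val <- mget(paste(pos, ref, alt, sep = ":"), envir = e, ifnotfound = NA_real_)[[1]]
  val
}

#' Filter by population alternate-allele frequency
#'
#' Screens for rarity: a variant is kept when its population frequency is
#' strictly below `max_af` (the conventional "< 1%" usage). Variants absent
#' from the table have no population frequency; `absent_policy` decides their
#' fate (default keep — novel variants are the interesting ones).
#'
#' @param vcf A `vcf_file`.
#' @param table An `aaf_table`.
#' @param max_af Frequency threshold in `[0, 1]` (strict).
#' @param absent_policy `"keep"` or `"drop"` for variants not in the table.
#' @return The filtered `vcf_file`.
#' @export
filter_aaf <- function(vcf, table, max_af, absent_policy = c("keep", "drop")) {
  absent_policy <- match.arg(absent_policy)
  stopifnot(max_af >= 0, max_af <= 1)
  keep <- vapply(vcf$variants, function(v) {
    afs <- vapply(v$alt, function(a) aaf_lookup(table, v$chrom, v$pos, v$ref, a),
                  numeric(1))
    if (!length(afs)) return(absent_policy == "keep")
    # per alternate allele; the record survives if any alt passes
    any(ifelse(is.na(afs), absent_policy == "keep", afs < max_af))
  }, logical(1))
  subset_variants(vcf, keep)
}

#' Filter by novelty
#'
#' A variant is novel iff its ID field is empty AND it is absent from the
#' known-variant resource.
#'
#' @param vcf A `vcf_file`.
#' @param known Either a character vector of known rsIDs or an `aaf_table`
#'   (membership is tested per alternate allele).
#' @param mode `"keep_novel"` or `"keep_known"`.
#' @return The filtered `vcf_file`.
#' @export
filter_novel <- function(vcf, known, mode = c("keep_novel", "keep_known")) {
  mode <- match.arg(mode)
  is_known <- vapply(vcf$variants, function(v) {
    if (!is.na(v$id)) return(TRUE)
    if (inherits(known, "aaf_table"))
      any(vapply(v$alt, function(a)
        !is.na(aaf_lookup(known, v$chrom, v$pos, v$ref, a)), logical(1)))
    else if (length(known)) v$id %in% known else FALSE
  }, logical(1))
  subset_variants(vcf, if (mode == "keep_novel") !is_known else is_known)
}

#' Same Variant Filter over multiple case files
#'
#' A variant (matched on chrom:pos:ref:alt) survives only when present in
#' every case stream.
#'
#' @param case_vcfs List of at least two `vcf_file`s.
#' @return The list with non-shared variants removed from every file.
#' @export
filter_same_variant <- function(case_vcfs) {
  if (length(case_vcfs) < 2)
    stop("Same Variant Filter needs at least 2 case files")
  key_sets <- lapply(case_vcfs, function(vcf)
    vapply(vcf$variants, variant_key, character(1)))
  shared <- Reduce(intersect, key_sets)
  Map(function(vcf, keys) subset_variants(vcf, keys %in% shared),
      case_vcfs, key_sets)
}

ann_genes <- function(v) if (n_ann(v) == 0) character() else unique(v$ann$gene)

#' Same Gene Filter over multiple case files
#'
#' A variant survives when at least one of its annotated gene symbols is
#' carried by some variant in EVERY case stream — different variants in the
#' same gene count as shared (the compound-heterozygote motivating case).
#' Matching is by gene symbol so isoform differences do not break sharing.
#'
#' @param case_vcfs List of at least two gene-annotated `vcf_file`s.
#' @return The list with variants outside shared genes removed.
#' @export
filter_same_gene <- function(case_vcfs) {
  if (length(case_vcfs) < 2)
    stop("Same Gene Filter needs at least 2 case files")
  gene_sets <- lapply(case_vcfs, function(vcf) {
    if (length(vcf$variants) &&
        !any(vapply(vcf$variants, function(v) n_ann(v) > 0, logical(1))))
      stop("Same Gene Filter needs gene-annotated input; run annotate_genes() first")
    unique(unlist(lapply(vcf$variants, ann_genes)))
  })
  shared <- Reduce(intersect, gene_sets)
  lapply(case_vcfs, function(vcf)
    subset_variants(vcf, vapply(vcf$variants, function(v)
      any(ann_genes(v) %in% shared), logical(1))))
}
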