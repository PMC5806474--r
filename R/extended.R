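# Post-filter fine annotation: isoform identity, protein-domain context and
# tissue-expression screening. These run on the small surviving variant set,
# after the heavy filtering stages.

#' Tag in-line annotations with RefSeq IDs and isoform status
#'
#' Each transcript annotation gains its RefSeq accession and a REF/ISO tag
#' (reference vs alternate isoform), so report rows can be isolated by
#' isoform class.
#'
#' @param vcf An annotated `vcf_file`.
#' @param transcripts A `transcript_set`.
#' @return The `vcf_file` with `refseq`/`iso` columns filled.
#' @export
annotate_isoform_ids <- function(vcf, transcripts) {
  ids <- vapply(transcripts, `[[`, character(1), "tx_id")
  vcf$variants <- lapply(vcf$variants, function(v) {
    if (n_ann(v) == 0) return(v)
    for (i in seq_len(nrow(v$ann))) {
      j <- match(v$ann$tx_id[i], ids)
      if (is.na(j)) {
        warning("transcript absent from table: ", v$ann$tx_id[i])
        v$ann$iso[i] <- "unknown"
        next
      }
      tx <- transcripts[[j]]
      v$ann$refseq[i] <- tx$refseq_id
      v$ann$iso[i] <- if (isTRUE(tx$is_reference_isoform)) "REF" else "ISO"
    }
    v
  })
  vcf
}

#' Load a protein-domain table
#'
#' Tab-separated columns: transcript id, domain name, aa_start, aa_end
#' (1-based inclusive amino-acid coordinates).
#'
#' @param path TSV path.
#' @return A data frame with columns `tx_id`, `domain`, `aa_start`, `aa_end`.
#' @export
load_domain_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("tx_id", "domain", "aa_start", "aa_end"),
                          colClasses = c("character", "character", "integer", "integer"),
                          quote = "")
  if (any(df$aa_start > df$aa_end))
    stop("domain table has aa_start > aa_end")
  df
}

protein_position <- function(aa_label) {
  m <- regmatches(aa_label, regexpr("[0-9]+", aa_label))
  if (!length(m)) NA_integer_ else as.integer(m)
}

#' Attach protein-domain context
#'
#' Coding annotations whose amino-acid position falls inside a domain
#' interval (boundaries inclusive) gain the domain name; non-coding
#' annotations are untouched.
#'
#' @param vcf A functionally annotated `vcf_file`.
#' @param domains Data frame from [load_domain_table()].
#' @return The `vcf_file` with `domain` entries filled.
#' @export
annotate_protein_domains <- function(vcf, domains) {
  vcf$variants <- lapply(vcf$variants, function(v) {
    if (n_ann(v) == 0) return(v)
    for (i in seq_len(nrow(v$ann))) {
      aa <- v$ann$aa[i]
      if (is.na(aa)) next
      pp <- protein_position(aa)
      if (is.na(pp)) next
      hit <- domains[domains$tx_id == v$ann$tx_id[i] &
                       domains$aa_start <= pp & domains$aa_end >= pp, ]
      if (nrow(hit))
        v$ann$domain[i] <- paste(unique(hit$domain), collapse = "&")
    }
    v
  })
  vcf
}

#' Load a tissue-expression table
#'
#' Tab-separated with a header row: first column `gene`, remaining columns
#' one per tissue; non-negative expression values in arbitrary units.
#'
#' @param path TSV path.
#' @return An `expression_table`: matrix genes x tissues.
#' @export
load_expression_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          quote = "", stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  if (any(mat < 0)) stop("expression table has negative values")
  structure(mat, class = c("expression_table", class(mat)))
}

#' Filter variants by tissue expression of their genes
#'
#' A variant is kept when any of its annotated genes satisfies the expression
#' bound in the chosen tissue. Genes absent from the table pass by default.
#'
#' @param vcf An annotated `vcf_file`.
#' @param table An `expression_table`.
#' @param tissue Tissue (column) name.
#' @param min_expr,max_expr Lower/upper bounds; supply at least one (both
#'   form a band).
#' @param absent_policy `"keep"` or `"drop"` for genes not in the table.
#' @return The filtered `vcf_file`.
#' @export
filter_gene_expression <- function(vcf, table, tissue, min_expr = NULL,
                                   max_expr = NULL,
                                   absent_policy = c("keep", "drop")) {
  absent_policy <- match.arg(absent_policy)
  if (is.null(min_expr) && is.null(max_expr))
    stop("supply min_expr, max_expr, or both")
  if (!tissue %in% colnames(table))
    stop("unknown tissue '", tissue, "'; available: ",
         paste(colnames(table), collapse = ", "))
  ok_expr <- function(e) {
    (is.null(min_expr) || e >= min_expr) && (is.null(max_expr) || e <= max_expr)
  }
  keep <- vapply(vcf$variants, function(v) {
    genes <- ann_genes(v)
    if (!length(genes)) return(FALSE)
    any(vapply(genes, function(g) {
      if (!g %in% rownames(table)) return(absent_policy == "keep")
      ok_expr(table[g, tissue])
    }, logical(1)))
  }, logical(1))
  subset_variants(vcf, keep)
}

#' Tissue-specificity score of a gene
#'
#' Expression in the target tissue divided by the mean expression across all
#' tissues: values near 1 indicate a housekeeping profile, large values a
#' strong organ-specific profile. Reported in the summary as a
#' prioritisation aid, never auto-filtered.
#'
#' @param table An `expression_table`.
#' @param gene Gene symbol.
#' @param tissue Tissue name.
#' @return A single numeric score (NA when the gene is absent).
#' @export
tissue_specificity <- function(table, gene, tissue) {
  if (!gene %in% rownames(table)) return(NA_real_)
  if (!tissue %in% colnames(table))
    stop("unknown tissue '", tissue, "'; available: ",
         paste(colnames(table), collapse = ", "))
  mu <- mean(table[gene, ])
  if (mu == 0) return(NA_real_)
  unname(table[gene, tissue] / mu)
}
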