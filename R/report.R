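# Summary report: one row per (variant, transcript annotation) across all
# final VCFs, with per-individual zygosity cells for cases and controls.
# The TSV is the machine-readable twin of the static HTML, which embeds
# client-side sorting and text search (e.g. "missense", "promoter_up", or
# "REF"/"ISO" to isolate reference/alternate isoform rows).

#' Generate the summary report
#'
#' @param vcfs Named list of final per-individual `vcf_file`s.
#' @param ped A `pedigree`.
#' @param tsv_path Output TSV path.
#' @param html_path Output HTML path (optional; `NULL` skips it).
#' @return The report data frame, invisibly.
#' @export
generate_report <- function(vcfs, ped, tsv_path, html_path = NULL) {
  cases <- intersect(ped$individual_id[ped$affected == "affected"], names(vcfs))
  controls <- setdiff(names(vcfs), cases)
  # union of variants over files, keyed; annotations from the first carrier
  by_key <- list(); key_order <- character()
  for (ind in names(vcfs)) {
    for (v in vcfs[[ind]]$variants) {
      k <- variant_key(v)
      if (is.null(by_key[[k]])) {
        by_key[[k]] <- list(v = v, zyg = list())
        key_order <- c(key_order, k)
      }
      if (n_ann(by_key[[k]]$v) == 0 && n_ann(v) > 0) by_key[[k]]$v <- v
      sample <- if (length(vcfs[[ind]]$samples)) vcfs[[ind]]$samples[1] else NA
      by_key[[k]]$zyg[[ind]] <- if (is.na(sample)) "MISSING" else zygosity_of(v, sample)
    }
  }
  rows <- list()
  for (k in key_order) {
    entry <- by_key[[k]]
    v <- entry$v
    if (n_ann(v) == 0) next
    zyg_cell <- function(ind) entry$zyg[[ind]] %||% "."
    for (i in seq_len(nrow(v$ann))) {
      a <- v$ann[i, ]
      row <- data.frame(
        chrom = v$chrom, pos = v$pos,
        rsid = if (is.na(v$id)) "." else v$id,
        gene = a$gene, gene_context = a$region,
        cdna_change = if (is.na(a$cdna)) "." else a$cdna,
        protein_change = if (is.na(a$aa)) "." else a$aa,
        functional_change = if (is.na(a$mut)) "." else a$mut,
        isoform = if (is.na(a$iso)) "." else a$iso,
        domain = if (is.na(a$domain)) "." else a$domain,
        model = v$model %||% ".",
        chet = v$chet %||% ".",
        stringsAsFactors = FALSE)
      for (ind in cases) row[[paste0("case_", ind)]] <- zyg_cell(ind)
      for (ind in controls) row[[paste0("control_", ind)]] <- zyg_cell(ind)
      rows[[length(rows) + 1L]] <- row
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else {
    cols <- c("chrom", "pos", "rsid", "gene", "gene_context", "cdna_change",
              "protein_change", "functional_change", "isoform", "domain",
              "model", "chet",
              paste0("case_", cases), paste0("control_", controls))
    as.data.frame(stats::setNames(rep(list(character()), length(cols)), cols),
                  stringsAsFactors = FALSE)
  }
  utils::write.table(report, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(html_path)) write_html_report(report, html_path)
  invisible(report)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

write_html_report <- function(report, path) {
  head_cells <- paste0("<th onclick=\"sortBy(", seq_along(report) - 1,
                       ")\">", html_escape(names(report)), "</th>", collapse = "")
  body_rows <- if (nrow(report)) paste(vapply(seq_len(nrow(report)), function(i) {
    cells <- paste0("<td>", html_escape(as.character(unlist(report[i, ]))), "</td>",
                    collapse = "")
    paste0("<tr>", cells, "</tr>")
  }, character(1)), collapse = "\n") else ""
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset='utf-8'><title>Variant report</title>",
    "<style>body{font-family:sans-serif}table{border-collapse:collapse}",
    "td,th{border:1px solid #999;padding:3px 6px;font-size:13px}",
    "th{cursor:pointer;background:#eee}</style></head><body>",
    "<h2>Surviving variants</h2>",
    "<input id='q' placeholder='search (e.g. missense, REF, promoter_up)' ",
    "oninput='filterRows()' style='width:30em;margin-bottom:6px'>",
    "<table id='t'><thead><tr>", head_cells, "</tr></thead>",
    "<tbody>", body_rows, "</tbody></table>",
    "<script>",
    "function filterRows(){var q=document.getElementById('q').value.toLowerCase();",
    "for(var r of document.querySelectorAll('#t tbody tr'))",
    "r.style.display=r.textContent.toLowerCase().includes(q)?'':'none';}",
    "var asc=true;",
    "function sortBy(c){var tb=document.querySelector('#t tbody');",
    "var rows=[...tb.rows];asc=!asc;",
    "rows.sort((a,b)=>{var x=a.cells[c].textContent,y=b.cells[c].textContent;",
    "var nx=parseFloat(x),ny=parseFloat(y);",
    "var cmp=(!isNaN(nx)&&!isNaN(ny))?nx-ny:x.localeCompare(y);",
    "return asc?cmp:-cmp;});",
    "for(var r of rows)tb.appendChild(r);}",
    "</script></body></html>")
  writeLines(c(html[1:2], html[-(1:2)]), path)
  invisible(path)
}
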