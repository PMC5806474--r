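# Gene model: transcript table -> queryable region map.
#
# Internal coordinates are 1-based inclusive everywhere (matching VCF); the
# UCSC refGene dialect's 0-based half-open coordinates are converted once at
# load time. Each transcript's span (plus its promoters) is carved into
# mutually disjoint intervals labelled exon / utr5 / utr3 / splice_donor /
# splice_acceptor / intron / promoter_up / promoter_down, strand-aware:
# the donor window is the 5' side of an intron in transcription direction,
# and promoter_up sits 5' of the transcription start.

REGION_CLASSES <- c("exon", "intron", "splice_donor", "splice_acceptor",
                    "utr5", "utr3", "promoter_up", "promoter_down")

#' Region-map parameters
#'
#' @param promoter_bp Promoter length in bp flanking the transcription start
#'   (upstream) and end (downstream). Default 500.
#' @param splice_bp Essential splice-site window, in intronic bases adjacent
#'   to each exon. Default 5.
#' @param enabled_regions Subset of region classes to emit.
#' @return A `gene_map_params` list.
#' @export
gene_map_params <- function(promoter_bp = 500, splice_bp = 5,
                            enabled_regions = REGION_CLASSES) {
  stopifnot(promoter_bp >= 0, splice_bp >= 0,
            all(enabled_regions %in% REGION_CLASSES))
  structure(list(promoter_bp = as.integer(promoter_bp),
                 splice_bp = as.integer(splice_bp),
                 enabled_regions = enabled_regions),
            class = "gene_map_params")
}

#' Load a refGene-dialect transcript table
#'
#' Expects tab-separated rows in UCSC refGene column order (an initial
#' integer `bin` column is detected and skipped): name, chrom, strand,
#' txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds, score,
#' name2 (gene symbol). exonStarts/exonEnds are comma-terminated lists.
#' Coordinates are converted from 0-based half-open to 1-based inclusive.
#' Non-coding transcripts (cdsStart == cdsEnd) keep `cds_start == cds_end`.
#' The first transcript per gene symbol in file order is flagged as the
#' reference isoform.
#'
#' @param path Path to the table.
#' @return A list of transcript records (class `transcript_set`).
#' @export
load_gene_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(structure(list(), class = "transcript_set"))
  rows <- strsplit(lines, "\t", fixed = TRUE)
  first <- rows[[1]]
  has_bin <- length(first) >= 13 && grepl("^[0-9]+$", first[1]) &&
    first[3 + 1] %in% c("+", "-")
  off <- if (has_bin) 1L else 0L
  seen_genes <- character()
  txs <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) < off + 12)
      stop("gene map parse error at row ", i, ": fewer than 12 columns")
    g <- function(j) r[off + j]
    ex_s <- as.integer(strsplit(g(9), ",", fixed = TRUE)[[1]])
    ex_e <- as.integer(strsplit(g(10), ",", fixed = TRUE)[[1]])
    if (length(ex_s) != length(ex_e))
      stop("gene map parse error at row ", i, ": exonStarts/exonEnds length mismatch")
    n_ex <- as.integer(g(8))
    if (!is.na(n_ex) && n_ex != length(ex_s))
      stop("gene map parse error at row ", i, ": exonCount disagrees with exon list")
    tx_start <- as.integer(g(4)) + 1L
    tx_end <- as.integer(g(5))
    cds_raw_s <- as.integer(g(6)); cds_raw_e <- as.integer(g(7))
    coding <- cds_raw_s != cds_raw_e
    cds_start <- if (coding) cds_raw_s + 1L else cds_raw_e
    cds_end <- cds_raw_e
    if (coding && (cds_start < tx_start || cds_end > tx_end))
      stop("gene map validation error at row ", i, ": CDS outside transcript bounds")
    exons <- cbind(start = ex_s + 1L, end = ex_e)
    if (any(exons[, "start"] > exons[, "end"]))
      stop("gene map validation error at row ", i, ": empty exon interval")
    if (is.unsorted(exons[, "start"]) ||
        (nrow(exons) > 1 && any(exons[-1, "start"] <= exons[-nrow(exons), "end"])))
      stop("gene map validation error at row ", i, ": exons overlap or are unsorted")
    gene <- g(12)
    txs[[i]] <- list(
      gene = gene, tx_id = g(1),
      refseq_id = if (grepl("^[NX][MR]_", g(1))) g(1) else NA_character_,
      chrom = g(2), strand = g(3),
      tx_start = tx_start, tx_end = tx_end,
      cds_start = cds_start, cds_end = cds_end, coding = coding,
      exons = exons,
      is_reference_isoform = !(gene %in% seen_genes)
    )
    seen_genes <- c(seen_genes, gene)
  }
  structure(txs, class = "transcript_set")
}

# disjoint labelled intervals for one transcript (data.frame start,end,region)
carve_transcript <- function(tx, params) {
  p <- params$promoter_bp; sw <- params$splice_bp
  out <- list()
  add <- function(s, e, region) {
    if (s <= e) out[[length(out) + 1L]] <<- data.frame(
      start = as.integer(s), end = as.integer(e), region = region,
      stringsAsFactors = FALSE)
  }
  ex <- tx$exons
  for (i in seq_len(nrow(ex))) {
    s <- ex[i, "start"]; e <- ex[i, "end"]
    if (!tx$coding) { add(s, e, "exon"); next }
    cs <- max(s, tx$cds_start); ce <- min(e, tx$cds_end)
    if (cs <= ce) add(cs, ce, "exon")
    if (s < tx$cds_start)
      add(s, min(e, tx$cds_start - 1L), if (tx$strand == "+") "utr5" else "utr3")
    if (e > tx$cds_end)
      add(max(s, tx$cds_end + 1L), e, if (tx$strand == "+") "utr3" else "utr5")
  }
  if (nrow(ex) > 1) {
    for (i in seq_len(nrow(ex) - 1)) {
      is <- ex[i, "end"] + 1L; ie <- ex[i + 1, "start"] - 1L
      len <- ie - is + 1L
      if (len <= 0) next
      lw <- min(sw, len)
      rw <- min(sw, len - lw)
      if (lw > 0) add(is, is + lw - 1L,
                      if (tx$strand == "+") "splice_donor" else "splice_acceptor")
      if (rw > 0) add(ie - rw + 1L, ie,
                      if (tx$strand == "+") "splice_acceptor" else "splice_donor")
      if (len > lw + rw) add(is + lw, ie - rw, "intron")
    }
  }
  if (p > 0) {
    if (tx$strand == "+") {
      add(max(1L, tx$tx_start - p), tx$tx_start - 1L, "promoter_up")
      add(tx$tx_end + 1L, tx$tx_end + p, "promoter_down")
    } else {
      add(tx$tx_end + 1L, tx$tx_end + p, "promoter_up")
      add(max(1L, tx$tx_start - p), tx$tx_start - 1L, "promoter_down")
    }
  }
  df <- do.call(rbind, out)
  df[df$region %in% params$enabled_regions, , drop = FALSE]
}

#' Build a queryable region map from transcripts
#'
#' Expands every transcript into disjoint labelled intervals (see module
#' notes) and indexes them per chromosome for overlap queries.
#'
#' @param transcripts A `transcript_set` from [load_gene_map()].
#' @param params A [gene_map_params()] object.
#' @return A `region_map` object.
#' @export
build_region_map <- function(transcripts, params = gene_map_params()) {
  pieces <- lapply(seq_along(transcripts), function(i) {
    df <- carve_transcript(transcripts[[i]], params)
    if (is.null(df) || !nrow(df)) return(NULL)
    df$tx <- i
    df$chrom <- norm_chrom(transcripts[[i]]$chrom)
    df
  })
  all <- do.call(rbind, pieces)
  if (is.null(all))
    all <- data.frame(start = integer(), end = integer(), region = character(),
                      tx = integer(), chrom = character(), stringsAsFactors = FALSE)
  index <- lapply(split(all, all$chrom), function(df) {
    list(df = df, ir = IRanges::IRanges(start = df$start, end = df$end))
  })
  structure(list(transcripts = transcripts, params = params, index = index),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  n <- sum(vapply(x$index, function(ch) nrow(ch$df), integer(1)))
  cat(sprintf("<region_map> %d transcripts, %d intervals on %d chromosome(s)\n",
              length(x$transcripts), n, length(x$index)))
  invisible(x)
}

# vectorised overlap query: data.frame(pos_index, tx, region) for one chrom
region_hits <- function(map, chrom, pos) {
  ch <- map$index[[norm_chrom(chrom)]]
  if (is.null(ch) || !length(pos))
    return(data.frame(pos_index = integer(), tx = integer(),
                      region = character(), stringsAsFactors = FALSE))
  q <- IRanges::IRanges(start = pos, width = 1L)
  hits <- IRanges::findOverlaps(q, ch$ir)
  data.frame(pos_index = S4Vectors::queryHits(hits),
             tx = ch$df$tx[S4Vectors::subjectHits(hits)],
             region = ch$df$region[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

#' Query the region map at a single position
#'
#' @param map A `region_map`.
#' @param chrom Chromosome name ("chr" prefix optional).
#' @param pos 1-based position.
#' @return A data frame with one row per overlapping (transcript, region)
#'   pair: columns `gene`, `tx_id`, `region`, `tx` (transcript index). Zero
#'   rows iff the position is wholly intergenic under the map's parameters.
#' @export
query_regions <- function(map, chrom, pos) {
  hits <- region_hits(map, chrom, pos)
  data.frame(
    gene = vapply(hits$tx, function(i) map$transcripts[[i]]$gene, character(1)),
    tx_id = vapply(hits$tx, function(i) map$transcripts[[i]]$tx_id, character(1)),
    region = hits$region, tx = hits$tx, stringsAsFactors = FALSE)
}

# coding-exon pieces in transcription order with cumulative cDNA offsets
cds_pieces <- function(tx) {
  ex <- tx$exons
  keep <- ex[, "end"] >= tx$cds_start & ex[, "start"] <= tx$cds_end
  ex <- ex[keep, , drop = FALSE]
  ex[, "start"] <- pmax(ex[, "start"], tx$cds_start)
  ex[, "end"] <- pmin(ex[, "end"], tx$cds_end)
  if (tx$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  widths <- ex[, "end"] - ex[, "start"] + 1L
  cbind(ex, before = cumsum(c(0L, widths))[seq_len(nrow(ex))])
}

# exonic bases of tx strictly 5' (side = "utr5") or 3' ("utr3") of the CDS,
# counted from the CDS boundary outward; used for c.-k / c.*k numbering
utr_exonic_len <- function(tx, side) {
  ex <- tx$exons
  if (side == "utr5") {
    if (tx$strand == "+")
      sum(pmax(0L, pmin(ex[, "end"], tx$cds_start - 1L) - ex[, "start"] + 1L))
    else
      sum(pmax(0L, ex[, "end"] - pmax(ex[, "start"], tx$cds_end + 1L) + 1L))
  } else {
    if (tx$strand == "+")
      sum(pmax(0L, ex[, "end"] - pmax(ex[, "start"], tx$cds_end + 1L) + 1L))
    else
      sum(pmax(0L, pmin(ex[, "end"], tx$cds_start - 1L) - ex[, "start"] + 1L))
  }
}

# structured cDNA coordinate for a genomic position within reach of tx.
# kind: cds (n = CDS base), utr5 (n = bases 5' of CDS start), utr3 (n = bases
# 3' of CDS end), intron (anchor = label of nearest exonic base, offset
# signed in transcription direction), n (non-coding transcript numbering)
cdna_coord <- function(tx, pos) {
  ex <- tx$exons
  in_exon <- any(pos >= ex[, "start"] & pos <= ex[, "end"])
  plus <- tx$strand == "+"
  exonic_between <- function(a, b) {  # exonic bases in genomic [a, b]
    if (a > b) return(0L)
    sum(pmax(0L, pmin(ex[, "end"], b) - pmax(ex[, "start"], a) + 1L))
  }
  if (!tx$coding) {
    # transcript numbering from transcription start over exonic bases
    if (in_exon) {
      n <- if (plus) exonic_between(tx$tx_start, pos) else exonic_between(pos, tx$tx_end)
      return(list(kind = "n", n = n))
    }
    if (plus && pos < tx$tx_start) return(list(kind = "n_up", n = tx$tx_start - pos))
    if (!plus && pos > tx$tx_end) return(list(kind = "n_up", n = pos - tx$tx_end))
    if (plus && pos > tx$tx_end) return(list(kind = "n_down", n = pos - tx$tx_end))
    if (!plus && pos < tx$tx_start) return(list(kind = "n_down", n = tx$tx_start - pos))
    return(intron_coord(tx, pos))
  }
  if (in_exon && pos >= tx$cds_start && pos <= tx$cds_end) {
    n <- if (plus) exonic_between(tx$cds_start, pos) else exonic_between(pos, tx$cds_end)
    return(list(kind = "cds", n = n))
  }
  five_side <- if (plus) pos < tx$cds_start else pos > tx$cds_end
  if (in_exon) {
    n <- if (plus) {
      if (five_side) exonic_between(pos, tx$cds_start - 1L)
      else exonic_between(tx$cds_end + 1L, pos)
    } else {
      if (five_side) exonic_between(tx$cds_end + 1L, pos)
      else exonic_between(pos, tx$cds_start - 1L)
    }
    return(list(kind = if (five_side) "utr5" else "utr3", n = n))
  }
  # outside the transcript span: promoter/flank, counted through the UTR
  if (plus && pos < tx$tx_start)
    return(list(kind = "utr5", n = utr_exonic_len(tx, "utr5") + (tx$tx_start - pos)))
  if (!plus && pos > tx$tx_end)
    return(list(kind = "utr5", n = utr_exonic_len(tx, "utr5") + (pos - tx$tx_end)))
  if (plus && pos > tx$tx_end)
    return(list(kind = "utr3", n = utr_exonic_len(tx, "utr3") + (pos - tx$tx_end)))
  if (!plus && pos < tx$tx_start)
    return(list(kind = "utr3", n = utr_exonic_len(tx, "utr3") + (tx$tx_start - pos)))
  intron_coord(tx, pos)
}

# intronic position: anchored to the nearest exon boundary (ties go to the
# transcriptionally upstream exon, the donor side)
intron_coord <- function(tx, pos) {
  ex <- tx$exons
  i <- which(ex[-nrow(ex), "end"] < pos & ex[-1, "start"] > pos)[1]
  left_e <- ex[i, "end"]; right_s <- ex[i + 1, "start"]
  dl <- pos - left_e; dr <- right_s - pos
  plus <- tx$strand == "+"
  use_left <- if (plus) dl <= dr else dl < dr  # tie -> upstream exon
  anchor_pos <- if (use_left) left_e else right_s
  offset <- if (use_left) dl else dr
  # sign: + if the anchor exon is 5' of the intron base in transcription
  anchor_is_upstream <- (use_left && plus) || (!use_left && !plus)
  anchor <- cdna_coord(tx, anchor_pos)
  list(kind = "intron", anchor = anchor,
       sign = if (anchor_is_upstream) "+" else "-", k = offset)
}

coord_to_label <- function(co) {
  switch(co$kind,
    cds = sprintf("c.%d", co$n),
    utr5 = sprintf("c.-%d", co$n),
    utr3 = sprintf("c.*%d", co$n),
    n = sprintf("n.%d", co$n),
    n_up = sprintf("n.-%d", co$n),
    n_down = sprintf("n.+%d", co$n),
    intron = {
      base <- sub("^[cn]\\.", "", coord_to_label(co$anchor))
      prefix <- if (co$anchor$kind %in% c("n", "n_up", "n_down")) "n." else "c."
      sprintf("%s%s%s%d", prefix, base, co$sign, co$k)
    })
}

#' Simplified HGVS-like cDNA position label
#'
#' Coding exonic bases are numbered `c.n` over CDS bases in transcription
#' direction; intronic bases anchor to the nearest exon boundary as `c.n+k`
#' (donor side) or `c.m-k` (acceptor side); bases 5' of the CDS start are
#' `c.-k` (positions upstream of the transcription start count the 5'UTR
#' exonic length plus the genomic distance) and 3' of the CDS end `c.*k`.
#'
#' @param tx A transcript record.
#' @param pos 1-based genomic position within the transcript span plus
#'   promoter reach.
#' @param promoter_bp Maximum flank reach, for bounds checking.
#' @return A single label string.
#' @export
cdna_position <- function(tx, pos, promoter_bp = 500) {
  if (pos < tx$tx_start - promoter_bp || pos > tx$tx_end + promoter_bp)
    stop(sprintf("position %d out of reach of transcript %s", pos, tx$tx_id))
  coord_to_label(cdna_coord(tx, pos))
}

#' Build a region map with a file-backed cache
#'
#' Region maps for a given (gene-map file, parameter) pair are deterministic,
#' so they are cached on disk keyed by a digest of the file contents and the
#' parameters, emulating pre-built static gene maps.
#'
#' @param gene_map_path Path to the transcript table.
#' @param params A [gene_map_params()].
#' @param cache_dir Directory for cached maps (created if needed).
#' @return A `region_map`.
#' @export
cached_region_map <- function(gene_map_path, params = gene_map_params(),
                              cache_dir = file.path(tempdir(), "varseg_maps")) {
  key <- stable_digest(list(file = unname(tools::md5sum(gene_map_path)),
                            params = unclass(params)))
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  cache <- file.path(cache_dir, paste0("region_map_", key, ".rds"))
  if (file.exists(cache)) return(readRDS(cache))
  map <- build_region_map(load_gene_map(gene_map_path), params)
  saveRDS(map, cache)
  map
}

# stable md5 digest of an R object via its canonical deparse
stable_digest <- function(x) {
  canon <- function(o) {
    if (is.list(o)) {
      if (!is.null(names(o))) o <- o[order(names(o))]
      lapply(o, canon)
    } else o
  }
  txt <- paste(deparse(canon(x)), collapse = "")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}
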