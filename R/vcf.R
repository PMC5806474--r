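# VCF-preserving I/O.
#
# A `vcf_file` is a plain list: `meta` (the ## header lines, verbatim),
# `samples` (genotype column names) and `variants` (a list of variant records).
# Every pipeline stage consumes and emits this structure so that intermediate
# results stay valid VCF at all times and one variant always occupies one line,
# however many transcripts it bisects.
#
# Per-transcript annotations live in-line as index-aligned, pipe-delimited
# INFO arrays under a reserved key family (VS_GENE, VS_REGION, ...): element i
# of every array refers to the same transcript context. The reader lifts these
# keys back out of INFO into the `ann` data frame, so a write/read cycle is
# lossless and foreign INFO keys are never touched.

VS_ANN_KEYS <- c(
  alt = "VS_ALT", gene = "VS_GENE", tx_id = "VS_TX", region = "VS_REGION",
  cdna = "VS_CDNA", mut = "VS_MUT", aa = "VS_AA", iso = "VS_ISO",
  refseq = "VS_RSQ", domain = "VS_DOM"
)
VS_ZYG_KEY <- "VS_ZYG"
VS_MODEL_KEY <- "VS_MODEL"
VS_CHET_KEY <- "VS_CHET"
VS_ALL_KEYS <- c(VS_ANN_KEYS, VS_ZYG_KEY, VS_MODEL_KEY, VS_CHET_KEY)

#' Construct an empty VCF container
#'
#' @param meta Character vector of `##` header lines.
#' @param samples Character vector of sample column names.
#' @param variants List of variant records.
#' @return A `vcf_file` object.
#' @export
vcf_file <- function(meta = character(), samples = character(), variants = list()) {
  structure(list(meta = meta, samples = samples, variants = variants),
            class = "vcf_file")
}

#' @export
print.vcf_file <- function(x, ...) {
  cat(sprintf("<vcf_file> %d variants, %d sample(s): %s\n",
              length(x$variants), length(x$samples),
              paste(x$samples, collapse = ", ")))
  invisible(x)
}

#' Number of variants in a VCF container
#' @param vcf A `vcf_file`.
#' @return Integer count.
#' @export
n_variants <- function(vcf) length(vcf$variants)

# strip an optional "chr" prefix so VCF/gene-map/FASTA dialects agree
norm_chrom <- function(chrom) sub("^chr", "", chrom, ignore.case = TRUE)

#' Canonical variant key
#'
#' Variants are matched across files on (chromosome, position, ref, alt),
#' with chromosome names normalised for the "chr" prefix.
#'
#' @param v A variant record.
#' @return A single string key.
#' @export
variant_key <- function(v) {
  paste(norm_chrom(v$chrom), v$pos, v$ref, paste(v$alt, collapse = ","), sep = ":")
}

empty_ann <- function() {
  data.frame(alt = character(), gene = character(), tx_id = character(),
             region = character(), cdna = character(), mut = character(),
             aa = character(), iso = character(), refseq = character(),
             domain = character(), stringsAsFactors = FALSE)
}

n_ann <- function(v) if (is.null(v$ann)) 0L else nrow(v$ann)

parse_call <- function(raw, format) {
  fields <- strsplit(raw, ":", fixed = TRUE)[[1]]
  get <- function(key) {
    i <- match(key, format)
    if (is.na(i) || i > length(fields) || fields[i] == ".") NA_character_ else fields[i]
  }
  gt <- get("GT")
  gt_alleles <- if (is.na(gt)) NULL else {
    a <- strsplit(gt, "[/|]")[[1]]
    suppressWarnings(as.integer(a))  # "." allele -> NA
  }
  ad <- get("AD")
  allele_depths <- if (is.na(ad)) NULL else suppressWarnings(as.integer(strsplit(ad, ",", fixed = TRUE)[[1]]))
  dp <- get("DP")
  gq <- get("GQ")
  list(gt = gt, gt_alleles = gt_alleles,
       depth = if (is.na(dp)) NA_integer_ else as.integer(dp),
       allele_depths = allele_depths,
       gq = if (is.na(gq)) NA_real_ else as.numeric(gq),
       raw = raw)
}

parse_info <- function(s) {
  if (s == "." || s == "") return(stats::setNames(character(), character()))
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  has_eq <- regexpr("=", parts, fixed = TRUE)
  keys <- ifelse(has_eq > 0, substr(parts, 1, has_eq - 1), parts)
  vals <- ifelse(has_eq > 0, substr(parts, has_eq + 1, nchar(parts)), NA_character_)
  stats::setNames(vals, keys)
}

split_pipe <- function(s) {
  out <- strsplit(s, "|", fixed = TRUE)[[1]]
  ifelse(out == ".", NA_character_, out)
}

# pull reserved VS_* keys out of a parsed INFO vector into structured slots
extract_vs_info <- function(v, samples) {
  info <- v$info
  present <- intersect(VS_ALL_KEYS, names(info))
  if (!length(present)) return(v)
  if (VS_ANN_KEYS[["gene"]] %in% present) {
    cols <- lapply(VS_ANN_KEYS, function(k) {
      if (k %in% names(info)) split_pipe(info[[k]]) else NULL
    })
    len <- length(cols$gene)
    filled <- lapply(names(VS_ANN_KEYS), function(nm) {
      col <- cols[[nm]]
      if (is.null(col)) col <- rep(NA_character_, len)
      if (length(col) != len)
        stop(sprintf("in-line annotation arrays are not index-aligned at %s:%d",
                     v$chrom, v$pos))
      col
    })
    names(filled) <- names(VS_ANN_KEYS)
    v$ann <- as.data.frame(filled, stringsAsFactors = FALSE)
  }
  if (VS_ZYG_KEY %in% present) {
    z <- split_pipe(info[[VS_ZYG_KEY]])
    if (length(samples) && length(z) == length(samples)) names(z) <- samples
    v$zyg <- z
  }
  if (VS_MODEL_KEY %in% present) v$model <- info[[VS_MODEL_KEY]]
  if (VS_CHET_KEY %in% present) v$chet <- info[[VS_CHET_KEY]]
  v$info <- info[setdiff(names(info), present)]
  v
}

#' Read a VCF file
#'
#' Parses a VCFv4.x file into a [vcf_file()] container. Multi-allelic records
#' are kept as one variant; unknown INFO/FORMAT keys are preserved verbatim.
#' Reserved `VS_*` INFO keys written by a previous run are recognised and
#' lifted back into the structured annotation slots; all other pre-existing
#' annotations are carried through untouched and never consumed.
#'
#' @param path Path to a VCF file.
#' @return A `vcf_file` object.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such VCF file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1], "##fileformat=VCF"))
    stop("malformed VCF header in ", path,
         ": first line must begin '##fileformat=VCF'")
  is_meta <- startsWith(lines, "##")
  meta_end <- which(!is_meta)[1]
  if (is.na(meta_end) || !startsWith(lines[meta_end], "#CHROM"))
    stop("malformed VCF header in ", path, ": missing #CHROM column line")
  meta <- lines[seq_len(meta_end - 1)]
  header_cols <- strsplit(lines[meta_end], "\t", fixed = TRUE)[[1]]
  samples <- if (length(header_cols) > 9) header_cols[10:length(header_cols)] else character()
  body <- lines[seq_along(lines) > meta_end]
  body <- body[nzchar(body)]
  variants <- vector("list", length(body))
  for (i in seq_along(body)) {
    cols <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(cols) < 8)
      stop(sprintf("VCF parse error at %s line %d: %d column(s), need >= 8",
                   path, meta_end + i, length(cols)))
    v <- list(
      chrom = cols[1],
      pos = as.integer(cols[2]),
      id = if (cols[3] == ".") NA_character_ else cols[3],
      ref = cols[4],
      alt = if (cols[5] == ".") character() else strsplit(cols[5], ",", fixed = TRUE)[[1]],
      qual = if (cols[6] == ".") NA_real_ else as.numeric(cols[6]),
      qual_raw = cols[6],
      filter = cols[7],
      info = parse_info(cols[8]),
      format = if (length(cols) >= 9) strsplit(cols[9], ":", fixed = TRUE)[[1]] else NULL,
      calls = NULL, ann = NULL, zyg = NULL
    )
    if (length(samples) && length(cols) >= 10) {
      calls <- lapply(cols[10:(9 + length(samples))], parse_call, format = v$format)
      names(calls) <- samples
      v$calls <- calls
    }
    variants[[i]] <- extract_vs_info(v, samples)
  }
  vcf_file(meta = meta, samples = samples, variants = variants)
}

serialize_info <- function(v) {
  info <- v$info
  add <- character()
  if (n_ann(v) > 0) {
    for (nm in names(VS_ANN_KEYS)) {
      col <- v$ann[[nm]]
      if (all(is.na(col)) && !nm %in% c("gene")) next
      add[[VS_ANN_KEYS[[nm]]]] <- paste(ifelse(is.na(col), ".", col), collapse = "|")
    }
  }
  if (!is.null(v$zyg))
    add[[VS_ZYG_KEY]] <- paste(ifelse(is.na(v$zyg), ".", v$zyg), collapse = "|")
  if (!is.null(v$model)) add[[VS_MODEL_KEY]] <- v$model
  if (!is.null(v$chet)) add[[VS_CHET_KEY]] <- v$chet
  all_info <- c(info, add)
  if (!length(all_info)) return(".")
  paste(ifelse(is.na(all_info), names(all_info),
               paste0(names(all_info), "=", all_info)), collapse = ";")
}

vs_header_lines <- function(keys) {
  desc <- c(
    VS_ALT = "Alternate allele of each in-line transcript annotation",
    VS_GENE = "Gene symbol per overlapped transcript",
    VS_TX = "Transcript identifier per overlapped transcript",
    VS_REGION = "Region class (exon/intron/splice/UTR/promoter) per transcript",
    VS_CDNA = "cDNA position label per transcript",
    VS_MUT = "Mutation type (synonymous/missense/nonsense/...) per transcript",
    VS_AA = "Protein change per transcript",
    VS_ISO = "REF for the reference isoform, ISO otherwise",
    VS_RSQ = "RefSeq accession per transcript",
    VS_DOM = "Protein domain overlapped by the variant, per transcript",
    VS_ZYG = "Base-count zygosity per sample, in sample column order",
    VS_MODEL = "Inheritance model under which the variant survived",
    VS_CHET = "Compound-het gene and partner variant keys"
  )
  vapply(keys, function(k) {
    num <- if (k %in% c(VS_MODEL_KEY)) "1" else "."
    sprintf('##INFO=<ID=%s,Number=%s,Type=String,Description="%s">', k, num, desc[[k]])
  }, character(1))
}

#' Write a VCF file
#'
#' Serialises a [vcf_file()] back to disk. Structured annotations are emitted
#' as pipe-delimited, index-aligned `VS_*` INFO arrays (one element per
#' transcript context) and declared in the header; a record with no
#' annotations is written without any `VS_*` key. Re-reading the output with
#' [read_vcf()] reconstructs every field.
#'
#' @param vcf A `vcf_file`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vcf, path) {
  used <- unique(unlist(lapply(vcf$variants, function(v) {
    keys <- character()
    if (n_ann(v) > 0) {
      for (nm in names(VS_ANN_KEYS)) {
        col <- v$ann[[nm]]
        if (!(all(is.na(col)) && nm != "gene")) keys <- c(keys, VS_ANN_KEYS[[nm]])
      }
    }
    if (!is.null(v$zyg)) keys <- c(keys, VS_ZYG_KEY)
    if (!is.null(v$model)) keys <- c(keys, VS_MODEL_KEY)
    if (!is.null(v$chet)) keys <- c(keys, VS_CHET_KEY)
    keys
  })))
  meta <- vcf$meta
  need <- setdiff(used, sub('^##INFO=<ID=([^,]+),.*$', '\\1', grep("^##INFO=", meta, value = TRUE)))
  if (length(need)) {
    hdr <- vs_header_lines(need[order(match(need, VS_ALL_KEYS))])
    last_info <- max(c(grep("^##INFO=", meta), length(meta)))
    meta <- append(meta, hdr, after = last_info)
  }
  header_cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (length(vcf$samples)) header_cols <- c(header_cols, "FORMAT", vcf$samples)
  body <- vapply(vcf$variants, function(v) {
    cols <- c(v$chrom, format(v$pos, scientific = FALSE),
              if (is.na(v$id)) "." else v$id,
              v$ref,
              if (length(v$alt)) paste(v$alt, collapse = ",") else ".",
              if (!is.null(v$qual_raw)) v$qual_raw
              else if (is.na(v$qual)) "." else format(v$qual, scientific = FALSE),
              v$filter,
              serialize_info(v))
    if (length(vcf$samples)) {
      cols <- c(cols, paste(v$format, collapse = ":"),
                vapply(vcf$samples, function(s) {
                  cl <- v$calls[[s]]
                  if (is.null(cl)) "." else cl$raw
                }, character(1)))
    }
    paste(cols, collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")  # binary mode: unix line endings everywhere
  on.exit(close(con))
  writeLines(c(meta, paste(header_cols, collapse = "\t"), body), con, sep = "\n")
  invisible(path)
}

default_chrom_order <- function(chroms) {
  u <- unique(norm_chrom(chroms))
  num <- suppressWarnings(as.integer(u))
  special <- match(u, c("X", "Y", "MT", "M"))
  rank <- ifelse(!is.na(num), num,
                 ifelse(!is.na(special), 1000L + special, NA_integer_))
  u[order(rank, u, na.last = TRUE)]
}

#' Sort variants by chromosome and position
#'
#' Stable sort by (chromosome order, position). Chromosome names are
#' normalised for the "chr" prefix before matching against `chrom_order`.
#'
#' @param vcf A `vcf_file`.
#' @param chrom_order Character vector giving the chromosome order. Defaults
#'   to the natural karyotype order (1..22, X, Y, MT) of the chromosomes
#'   observed in the file.
#' @return The sorted `vcf_file`.
#' @export
sort_variants <- function(vcf, chrom_order = NULL) {
  chroms <- vapply(vcf$variants, function(v) norm_chrom(v$chrom), character(1))
  if (is.null(chrom_order)) chrom_order <- default_chrom_order(chroms)
  chrom_order <- norm_chrom(chrom_order)
  idx <- match(chroms, chrom_order)
  if (anyNA(idx)) {
    bad <- unique(chroms[is.na(idx)])
    stop("chromosome(s) not in chrom_order: ", paste(bad, collapse = ", "))
  }
  pos <- vapply(vcf$variants, function(v) v$pos, integer(1))
  vcf$variants <- vcf$variants[order(idx, pos)]
  vcf
}

#' Subset a VCF container by a logical or index vector
#' @param vcf A `vcf_file`.
#' @param keep Logical vector over variants, or integer indices.
#' @return The subsetted `vcf_file`.
#' @export
subset_variants <- function(vcf, keep) {
  vcf$variants <- vcf$variants[keep]
  vcf
}

#' Parse a PED pedigree file
#'
#' Whitespace-delimited rows of at least six columns: family id, individual
#' id, father id, mother id, sex (1 = male, 2 = female, other = unknown) and
#' phenotype (2 = affected, 1 = unaffected, other = unknown). "0" parent ids
#' are missing. An optional seventh column links each individual to a VCF
#' path.
#'
#' @param path Path to the PED file.
#' @return A data frame of class `pedigree` with columns `family_id`,
#'   `individual_id`, `father_id`, `mother_id`, `sex`, `affected`, `vcf_path`.
#' @export
parse_pedigree <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- strsplit(lines, "[ \t]+")
  short <- which(lengths(rows) < 6)
  if (length(short))
    stop("pedigree row ", short[1], " has fewer than 6 columns")
  ped <- data.frame(
    family_id = vapply(rows, `[`, character(1), 1),
    individual_id = vapply(rows, `[`, character(1), 2),
    father_id = vapply(rows, `[`, character(1), 3),
    mother_id = vapply(rows, `[`, character(1), 4),
    sex_code = vapply(rows, `[`, character(1), 5),
    pheno_code = vapply(rows, `[`, character(1), 6),
    vcf_path = vapply(rows, function(r) if (length(r) >= 7) r[7] else NA_character_, character(1)),
    stringsAsFactors = FALSE
  )
  rel <- !is.na(ped$vcf_path) & !grepl("^/", ped$vcf_path)
  ped$vcf_path[rel] <- file.path(dirname(normalizePath(path)), ped$vcf_path[rel])
  ped$father_id[ped$father_id == "0"] <- NA_character_
  ped$mother_id[ped$mother_id == "0"] <- NA_character_
  ped$sex <- ifelse(ped$sex_code == "1", "male",
                    ifelse(ped$sex_code == "2", "female", "unknown"))
  ped$affected <- ifelse(ped$pheno_code == "2", "affected",
                         ifelse(ped$pheno_code == "1", "unaffected", "unknown"))
  ped$sex_code <- NULL
  ped$pheno_code <- NULL
  for (fam in unique(ped$family_id)) {
    sub <- ped[ped$family_id == fam, ]
    if (anyDuplicated(sub$individual_id))
      stop("duplicate individual id in family ", fam, ": ",
           sub$individual_id[duplicated(sub$individual_id)][1])
    for (par in c("father_id", "mother_id")) {
      dangling <- setdiff(stats::na.omit(sub[[par]]), sub$individual_id)
      if (length(dangling))
        stop("pedigree structural error in family ", fam,
             ": parent id not found: ", dangling[1])
    }
    # no individual may be its own ancestor
    for (id in sub$individual_id) {
      seen <- character()
      frontier <- id
      while (length(frontier)) {
        cur <- frontier[1]; frontier <- frontier[-1]
        row <- sub[sub$individual_id == cur, ]
        parents <- stats::na.omit(c(row$father_id, row$mother_id))
        if (id %in% parents)
          stop("pedigree structural error in family ", fam, ": ", id,
               " is its own ancestor")
        frontier <- c(frontier, setdiff(parents, seen))
        seen <- c(seen, parents)
      }
    }
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Rename case VCFs to match their pedigree identity
#'
#' Copies each linked VCF into `dir` under the conventional
#' `<family>_<individual>.vcf` name, so downstream stages can address files
#' by pedigree identity.
#'
#' @param ped A `pedigree` with `vcf_path` entries.
#' @param dir Target directory (created if needed).
#' @return The pedigree with `vcf_path` rewritten to the new locations.
#' @export
intake_pedigree_vcfs <- function(ped, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(ped))) {
    if (is.na(ped$vcf_path[i])) next
    dest <- file.path(dir, sprintf("%s_%s.vcf", ped$family_id[i], ped$individual_id[i]))
    file.copy(ped$vcf_path[i], dest, overwrite = TRUE)
    ped$vcf_path[i] <- dest
  }
  ped
}
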