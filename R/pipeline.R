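# Configuration-driven chaining of the annotation/filter/inheritance stages
# with per-stage provenance and resume semantics.
#
# Every stage reads its predecessor's per-individual VCFs and writes new
# ones into its own directory, so results can be extracted at any point of
# an ongoing analysis. Each output carries a ##VS_STAGE provenance header
# recording the stage index, name and a hash chaining the canonicalised
# parameters, the upstream hash and the md5 of any resource file the stage
# consumes; a re-run skips every leading stage whose expected hash matches
# the one on disk and recomputes from the first mismatch onward.

STAGE_REQUIRES <- list(
  add_genes = character(), add_function = "add_genes",
  add_zygosity = character(),
  filter_location = character(), filter_depth = character(),
  filter_quality = character(), filter_mutation_type = "add_function",
  filter_aaf = character(), filter_novel = character(),
  filter_same_variant = character(), filter_same_gene = "add_genes",
  inheritance = c("add_genes", "add_zygosity"), mosaic = character(),
  isoform_context = "add_genes", protein_context = "add_function",
  gene_expression = "add_genes"
)

STAGE_RESOURCES <- list(
  add_genes = "gene_map", add_function = c("gene_map", "genome"),
  filter_aaf = "aaf_table", filter_novel = "aaf_table",
  filter_location = "regions", inheritance = "pedigree",
  mosaic = "pedigree", isoform_context = "gene_map",
  protein_context = "domain_table", gene_expression = "expression_table"
)

#' Read a pipeline configuration file
#'
#' A single declarative YAML file: `run_id`, `output_dir`, `pedigree`,
#' resource paths (`genome`, `gene_map`, `aaf_table`, `domain_table`,
#' `expression_table`, `regions`) and an ordered `stages` list of
#' `{name, params}` entries. Relative paths resolve against the config
#' file's directory.
#'
#' @param path YAML path.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  config <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("pedigree", "genome", "gene_map", "aaf_table", "domain_table",
                "expression_table", "regions", "output_dir")) {
    if (!is.null(config[[key]]) && !grepl("^/", config[[key]]))
      config[[key]] <- file.path(base, config[[key]])
  }
  structure(config, class = "pipeline_config")
}

#' Validate a configuration into an executable plan
#'
#' Rejects unknown stages, filter-before-annotation orderings (any stage
#' whose required annotator has not run earlier), inheritance stages without
#' a pedigree containing an affected individual, and multi-file filters with
#' fewer than two case files.
#'
#' @param config A `pipeline_config` (or plain list with the same fields).
#' @return A `pipeline_plan`.
#' @export
validate_config <- function(config) {
  stages <- config$stages
  if (is.null(stages) || !length(stages)) stop("config error: no stages")
  ped <- if (!is.null(config$pedigree)) parse_pedigree(config$pedigree) else NULL
  n_cases <- if (is.null(ped)) 0L else sum(ped$affected == "affected" & !is.na(ped$vcf_path))
  seen <- character()
  for (i in seq_along(stages)) {
    st <- stages[[i]]
    if (is.null(st$name) || !st$name %in% names(STAGE_REQUIRES))
      stop("config error: unknown stage '", st$name, "' at position ", i)
    missing <- setdiff(STAGE_REQUIRES[[st$name]], seen)
    if (length(missing))
      stop("ordering error: stage '", st$name, "' requires '",
           missing[1], "' to run earlier")
    if (st$name %in% c("inheritance", "mosaic")) {
      if (is.null(ped)) stop("config error: stage '", st$name, "' needs a pedigree")
      if (!any(ped$affected == "affected"))
        stop("config error: stage '", st$name,
             "' needs a pedigree with at least one affected individual")
    }
    if (st$name %in% c("filter_same_variant", "filter_same_gene") && n_cases < 2)
      stop("config error: stage '", st$name, "' needs at least 2 case files")
    seen <- c(seen, st$name)
  }
  structure(list(config = config, ped = ped, stages = stages),
            class = "pipeline_plan")
}

stage_hash <- function(name, params, upstream, config) {
  res <- list()
  for (key in STAGE_RESOURCES[[name]]) {
    if (!is.null(config[[key]]) && file.exists(config[[key]]))
      res[[key]] <- unname(tools::md5sum(config[[key]]))
  }
  stable_digest(list(name = name, params = params, upstream = upstream,
                     resources = res))
}

provenance_line <- function(idx, name, hash)
  sprintf("##VS_STAGE=%d:%s:%s", idx, name, hash)

last_provenance <- function(path) {
  meta <- grep("^##VS_STAGE=", readLines(path, warn = FALSE), value = TRUE)
  if (!length(meta)) return(NULL)
  sub("^##VS_STAGE=", "", meta[length(meta)])
}

stage_dir <- function(out_root, idx, name)
  file.path(out_root, sprintf("stage_%02d_%s", idx, name))

# apply one stage to the named list of per-individual vcf objects
stage_apply <- function(name, params, vcfs, ped, config, resources) {
  cases <- ped$individual_id[ped$affected == "affected"]
  cases <- intersect(cases, names(vcfs))
  per_file <- function(f) lapply(vcfs, f)
  switch(name,
    add_genes = per_file(function(v)
      annotate_genes(v, resources$map,
                     keep_intergenic = isTRUE(params$keep_intergenic))),
    add_function = per_file(function(v)
      annotate_functions(v, resources$map, resources$genome)),
    add_zygosity = per_file(function(v)
      assign_zygosity(v, lo = params$lo %||% 0.15, hi = params$hi %||% 0.85)),
    filter_location = per_file(function(v)
      filter_physical_location(v, resources$regions, mode = params$mode %||% "keep")),
    filter_depth = per_file(function(v)
      filter_read_depth(v, params$min_dp %||% 10,
                        scope = params$scope %||% "any_sample")),
    filter_quality = per_file(function(v)
      filter_call_quality(v, params$min_qual %||% 20)),
    filter_mutation_type = per_file(function(v)
      filter_mutation_type(v, params$keep_types)),
    filter_aaf = per_file(function(v)
      filter_aaf(v, resources$aaf, params$max_af %||% 0.01,
                 absent_policy = params$absent_policy %||% "keep")),
    filter_novel = per_file(function(v)
      filter_novel(v, resources$aaf %||% character(),
                   mode = params$mode %||% "keep_novel")),
    filter_same_variant = {
      out <- vcfs
      out[cases] <- filter_same_variant(vcfs[cases])
      out
    },
    filter_same_gene = {
      out <- vcfs
      out[cases] <- filter_same_gene(vcfs[cases])
      out
    },
    inheritance = apply_inheritance(vcfs, ped, params$model)$vcfs,
    mosaic = apply_inheritance(vcfs, ped, "mosaic",
                               mosaic_window = c(params$min_af %||% 0.10,
                                                 params$max_af %||% 0.35))$vcfs,
    isoform_context = per_file(function(v)
      annotate_isoform_ids(v, resources$transcripts)),
    protein_context = per_file(function(v)
      annotate_protein_domains(v, resources$domains)),
    gene_expression = per_file(function(v)
      filter_gene_expression(v, resources$expr, params$tissue,
                             min_expr = params$min_expr,
                             max_expr = params$max_expr)),
    stop("unknown stage: ", name))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_stage_resources <- function(plan, needed) {
  config <- plan$config
  res <- list()
  if (any(needed %in% c("add_genes", "add_function", "isoform_context"))) {
    params <- NULL
    for (st in plan$stages) if (st$name == "add_genes") params <- st$params
    gp <- gene_map_params(promoter_bp = params$promoter_bp %||% 500,
                          splice_bp = params$splice_bp %||% 5)
    res$map <- build_region_map(load_gene_map(config$gene_map), gp)
    res$transcripts <- res$map$transcripts
  }
  if ("add_function" %in% needed) res$genome <- load_genome(config$genome)
  if (any(needed %in% c("filter_aaf", "filter_novel")) && !is.null(config$aaf_table))
    res$aaf <- load_aaf_table(config$aaf_table)
  if ("filter_location" %in% needed && !is.null(config$regions))
    res$regions <- read_bed(config$regions)
  if ("protein_context" %in% needed) res$domains <- load_domain_table(config$domain_table)
  if ("gene_expression" %in% needed) res$expr <- load_expression_table(config$expression_table)
  res
}

#' Run (or resume) a pipeline plan
#'
#' Executes the stages in order against the pedigree-linked input VCFs.
#' Stage 0 is the intake step: inputs are renamed to
#' `<family>_<individual>.vcf`, position-sorted and stamped with the input
#' provenance hash. Every stage writes its outputs into its own directory
#' under `output_dir/run_id`, appending a `##VS_STAGE` provenance header.
#' When `resume = TRUE`, leading stages whose on-disk provenance matches the
#' expected hash chain are skipped ("the same data is never processed
#' twice"); the first mismatching stage and everything downstream re-run.
#' A structured log records per-stage input/output variant counts and wall
#' time; the final stage outputs feed [generate_report()].
#'
#' @param plan A `pipeline_plan` from [validate_config()].
#' @param resume Skip stages already computed under identical provenance?
#' @return A `pipeline_run`: `dir`, `log` (data frame), `executed`
#'   (stage labels actually computed), `final_paths`, `report_tsv`,
#'   `report_html`.
#' @export
run_pipeline <- function(plan, resume = FALSE) {
  config <- plan$config
  ped <- plan$ped
  if (is.null(ped)) stop("run_pipeline needs a pedigree")
  linked <- ped[!is.na(ped$vcf_path), ]
  if (!nrow(linked)) stop("pedigree links no VCF files")
  out_root <- file.path(config$output_dir, config$run_id %||% "run")
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
  inds <- linked$individual_id
  input_hash <- stable_digest(list(
    inputs = unname(tools::md5sum(linked$vcf_path)),
    pedigree = unname(tools::md5sum(config$pedigree))))

  hashes <- character(length(plan$stages) + 1L)
  hashes[1] <- stage_hash("add_zygosity", list(intake = TRUE), input_hash, config)
  for (i in seq_along(plan$stages))
    hashes[i + 1] <- stage_hash(plan$stages[[i]]$name, plan$stages[[i]]$params,
                                hashes[i], config)

  labels <- c("input", vapply(plan$stages, `[[`, character(1), "name"))
  dirs <- vapply(seq_along(labels), function(i)
    stage_dir(out_root, i - 1L, labels[i]), character(1))
  expected_files <- lapply(seq_along(labels), function(i)
    file.path(dirs[i], sprintf("%s_%s.vcf", linked$family_id, inds)))

  stage_ok <- function(i) {
    files <- expected_files[[i]]
    all(file.exists(files)) &&
      all(vapply(files, function(f) {
        pv <- last_provenance(f)
        !is.null(pv) && identical(pv, sprintf("%d:%s:%s", i - 1L, labels[i], hashes[i]))
      }, logical(1)))
  }
  start_at <- 1L
  if (resume) {
    while (start_at <= length(labels) && stage_ok(start_at)) start_at <- start_at + 1L
  }

  needed <- if (start_at > length(labels)) character()
            else labels[seq(start_at, length(labels))]
  resources <- load_stage_resources(plan, needed)

  log <- data.frame(stage = labels, executed = FALSE,
                    n_in = NA_integer_, n_out = NA_integer_,
                    seconds = NA_real_, stringsAsFactors = FALSE)
  executed <- character()
  vcfs <- NULL
  read_stage <- function(i) {
    out <- lapply(expected_files[[i]], read_vcf)
    names(out) <- inds
    out
  }
  if (start_at > 1L && start_at <= length(labels)) vcfs <- read_stage(start_at - 1L)

  for (i in seq_along(labels)) {
    if (i < start_at) next
    t0 <- proc.time()[["elapsed"]]
    if (i == 1L) {
      vcfs <- lapply(linked$vcf_path, function(p) sort_variants(read_vcf(p)))
      names(vcfs) <- inds
      n_in <- sum(vapply(vcfs, n_variants, integer(1)))
    } else {
      n_in <- sum(vapply(vcfs, n_variants, integer(1)))
      st <- plan$stages[[i - 1L]]
      vcfs <- tryCatch(
        stage_apply(st$name, st$params, vcfs, ped, config, resources),
        error = function(e) stop("stage '", st$name, "' failed: ",
                                 conditionMessage(e), call. = FALSE))
    }
    dir.create(dirs[i], showWarnings = FALSE, recursive = TRUE)
    for (j in seq_along(inds)) {
      v <- vcfs[[inds[j]]]
      v$meta <- c(v$meta, provenance_line(i - 1L, labels[i], hashes[i]))
      write_vcf(v, expected_files[[i]][j])
    }
    log$executed[i] <- TRUE
    log$n_in[i] <- n_in
    log$n_out[i] <- sum(vapply(vcfs, n_variants, integer(1)))
    log$seconds[i] <- proc.time()[["elapsed"]] - t0
    executed <- c(executed, labels[i])
  }

  final_idx <- length(labels)
  if (is.null(vcfs)) vcfs <- read_stage(final_idx)
  report_tsv <- file.path(out_root, "report.tsv")
  report_html <- file.path(out_root, "report.html")
  generate_report(vcfs, ped, report_tsv, report_html)
  utils::write.table(log, file.path(out_root, "log.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  structure(list(dir = out_root, log = log, executed = executed,
                 final_paths = expected_files[[final_idx]],
                 final_vcfs = vcfs,
                 report_tsv = report_tsv, report_html = report_html),
            class = "pipeline_run")
}

#' Resume a pipeline, skipping stages already computed
#'
#' Equivalent to `run_pipeline(plan, resume = TRUE)`: stages whose on-disk
#' provenance hash matches the expected chain are not recomputed.
#'
#' @param plan A `pipeline_plan`.
#' @return A `pipeline_run`; its `executed` field lists only the stages that
#'   actually ran (empty for an identical re-run).
#' @export
resume_pipeline <- function(plan) run_pipeline(plan, resume = TRUE)

#' Plot per-stage variant progression
#'
#' Renders the waterfall of variant counts through the pipeline stages from
#' a run's log.
#'
#' @param log The `log` data frame of a `pipeline_run`.
#' @param ... Passed to [graphics::barplot()].
#' @return The bar midpoints, invisibly.
#' @export
plot_variant_progression <- function(log, ...) {
  graphics::barplot(log$n_out, names.arg = log$stage, las = 2,
                    ylab = "variants remaining", ...)
}
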