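# Trait-penetrance filtering over pedigree-linked multi-file variant sets.
#
# All rules operate on a FamilyGenotypeView: a per-variant-key matrix of
# zygosities across the family's individuals, with roles (affected,
# unaffected, father, mother) taken from the pedigree. With one single-sample
# VCF per individual, an individual lacking a record at a key is MISSING,
# which is treated as non-informative: it never eliminates a key on its own
# (coverage gaps should not create false negatives) but an affected
# individual must positively carry a candidate allele.

CARRIER <- c("HET", "HOM_ALT")

#' Build a family genotype view
#'
#' @param ped A `pedigree` (one family).
#' @param vcfs Named list of `vcf_file`s, names = individual ids. Each file
#'   is expected to hold that individual's calls (single-sample).
#' @return A `family_view`: zygosity matrix (keys x individuals), per-key
#'   chromosome/genes, and pedigree roles.
#' @export
family_genotype_view <- function(ped, vcfs) {
  if (!all(names(vcfs) %in% ped$individual_id))
    stop("vcfs contain individuals absent from the pedigree: ",
         paste(setdiff(names(vcfs), ped$individual_id), collapse = ", "))
  keys <- character(); chrom <- character(); genes <- list()
  per_ind <- lapply(vcfs, function(vcf) {
    sample <- if (length(vcf$samples)) vcf$samples[1] else NA_character_
    k <- vapply(vcf$variants, variant_key, character(1))
    z <- vapply(seq_along(vcf$variants), function(i)
      if (is.na(sample)) "MISSING" else zygosity_of(vcf$variants[[i]], sample),
      character(1))
    list(keys = k, zyg = stats::setNames(z, k), variants = vcf$variants)
  })
  all_keys <- unique(unlist(lapply(per_ind, `[[`, "keys")))
  zmat <- matrix("MISSING", nrow = length(all_keys), ncol = length(vcfs),
                 dimnames = list(all_keys, names(vcfs)))
  key_chrom <- stats::setNames(character(length(all_keys)), all_keys)
  key_genes <- stats::setNames(vector("list", length(all_keys)), all_keys)
  for (ind in names(per_ind)) {
    pi <- per_ind[[ind]]
    zmat[pi$keys, ind] <- unname(pi$zyg[pi$keys])
    for (i in seq_along(pi$keys)) {
      k <- pi$keys[i]
      key_chrom[[k]] <- norm_chrom(pi$variants[[i]]$chrom)
      key_genes[[k]] <- unique(c(key_genes[[k]], ann_genes(pi$variants[[i]])))
    }
  }
  fam <- ped[ped$individual_id %in% names(vcfs) | ped$affected != "unknown", , drop = FALSE]
  structure(list(ped = ped, zyg = zmat, chrom = key_chrom, genes = key_genes,
                 individuals = names(vcfs),
                 affected = intersect(ped$individual_id[ped$affected == "affected"], names(vcfs)),
                 unaffected = intersect(ped$individual_id[ped$affected == "unaffected"], names(vcfs))),
            class = "family_view")
}

view_keys <- function(view) rownames(view$zyg)

zyg_at <- function(view, key, ind) {
  if (!ind %in% colnames(view$zyg)) return("MISSING")
  view$zyg[key, ind]
}

parents_of <- function(view, ind) {
  row <- view$ped[view$ped$individual_id == ind, ]
  stats::setNames(c(row$father_id, row$mother_id), c("father", "mother"))
}

genotyped <- function(view, key, ind) {
  !is.na(ind) && ind %in% colnames(view$zyg) && zyg_at(view, key, ind) != "MISSING"
}

is_affected <- function(view, ind) ind %in% view$ped$individual_id[view$ped$affected == "affected"]

sex_of <- function(view, ind) {
  s <- view$ped$sex[view$ped$individual_id == ind]
  if (length(s)) s else "unknown"
}

carries <- function(z) z %in% CARRIER

#' Autosomal dominant filter
#'
#' Under complete penetrance a single mutant allele causes the phenotype:
#' every affected individual must carry the alternate allele (HET or
#' HOM_ALT), no unaffected individual may carry it, and whenever an
#' affected's parents are genotyped at least one affected parent must also
#' carry it (affected individuals have affected parents). In de novo mode
#' the parental-transmission requirement is replaced by screening all
#' common affected variants against the unaffected controls: any carrying
#' control eliminates the key. Missing genotypes are non-informative.
#'
#' @param view A `family_view` (autosomal keys; X handled by
#'   [filter_x_dominant()]).
#' @param de_novo De novo mode flag.
#' @param incomplete_penetrance Allow unaffected carriers (non-de-novo mode).
#' @return Character vector of surviving variant keys.
#' @export
filter_autosomal_dominant <- function(view, de_novo = FALSE,
                                      incomplete_penetrance = FALSE) {
  if (!length(view$affected)) stop("no affected individuals in the pedigree")
  keep <- vapply(view_keys(view), function(k) {
    zyg_aff <- vapply(view$affected, function(a) zyg_at(view, k, a), character(1))
    if (!all(carries(zyg_aff))) return(FALSE)
    for (u in view$unaffected) {
      zu <- zyg_at(view, k, u)
      if (carries(zu) && (de_novo || !incomplete_penetrance)) return(FALSE)
    }
    if (!de_novo) {
      for (a in view$affected) {
        par <- parents_of(view, a)
        gtyped <- par[vapply(par, function(p) genotyped(view, k, p), logical(1))]
        if (!length(gtyped)) next  # singleton/ungenotyped parents: carrier-presence rule
        aff_parents <- gtyped[vapply(gtyped, function(p) is_affected(view, p), logical(1))]
        if (!length(aff_parents)) return(FALSE)
        if (!any(vapply(aff_parents, function(p) carries(zyg_at(view, k, p)), logical(1))))
          return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  view_keys(view)[keep]
}

# shared recessive helpers ---------------------------------------------------

# does `ind` satisfy the homozygous-alt requirement at key k (hemizygous
# males on X: any alt-carrying call counts)
hom_requirement <- function(view, k, ind, x_linked) {
  z <- zyg_at(view, k, ind)
  if (x_linked && sex_of(view, ind) == "male") return(carries(z))
  z == "HOM_ALT"
}

#' Autosomal recessive filter (homozygous and compound-heterozygous paths)
#'
#' HOM path: a key survives when every affected individual is homozygous for
#' the alternate allele; each genotyped parent of an affected must be a
#' heterozygous carrier; and any unaffected individual homozygous for the
#' allele eliminates it (unaffected HET carriers are expected and allowed).
#'
#' C-HET path: per gene, at least two distinct keys heterozygous in every
#' affected individual are required. When both parents are genotyped the two
#' variants must be of opposite parental origin and no single parent may
#' carry both members of a pair (such a parent would be an unaffected
#' compound heterozygote, contradicting the model). Candidate keys
#' homozygous in an unaffected control are discarded. With ungenotyped
#' parents the rule degrades to the shared-HET requirement with unknown
#' origin.
#'
#' @param view A `family_view`.
#' @param x_linked Internal: apply hemizygous-male handling (see
#'   [filter_x_recessive()]).
#' @return A list with `hom_keys` (character vector) and `chet_genes` (list
#'   of records: `gene`, `keys`, `origin`).
#' @export
filter_autosomal_recessive <- function(view, x_linked = FALSE) {
  if (!length(view$affected)) stop("no affected individuals in the pedigree")
  keys <- view_keys(view)
  # --- HOM path
  hom <- vapply(keys, function(k) {
    if (!all(vapply(view$affected, function(a) hom_requirement(view, k, a, x_linked),
                    logical(1)))) return(FALSE)
    for (u in view$unaffected) {
      if (hom_requirement(view, k, u, x_linked)) return(FALSE)
    }
    for (a in view$affected) {
      if (x_linked && sex_of(view, a) == "male") {
        # only the mother transmits a son's X
        m <- parents_of(view, a)[["mother"]]
        if (genotyped(view, k, m) && !carries(zyg_at(view, k, m))) return(FALSE)
        next
      }
      par <- parents_of(view, a)
      for (p in par) {
        if (!genotyped(view, k, p)) next
        zp <- zyg_at(view, k, p)
        if (x_linked && sex_of(view, p) == "male") {
          if (!carries(zp)) return(FALSE)  # affected daughter needs a carrier father
        } else if (zp != "HET") return(FALSE)  # carrier-parent assumption
      }
    }
    TRUE
  }, logical(1))
  # --- C-HET path
  chet_affected <- if (x_linked)
    view$affected[vapply(view$affected, function(a) sex_of(view, a) != "male", logical(1))]
  else view$affected
  chet_genes <- list()
  if (length(chet_affected) && length(keys)) {
    gene_keys <- split(rep(keys, lengths(view$genes)), unlist(view$genes))
    for (gene in names(gene_keys)) {
      cand <- unique(gene_keys[[gene]])
      cand <- cand[vapply(cand, function(k) {
        all(vapply(chet_affected, function(a) zyg_at(view, k, a) == "HET", logical(1))) &&
          (!x_linked || all(vapply(view$affected, function(a)
            sex_of(view, a) != "male" || carries(zyg_at(view, k, a)), logical(1)))) &&
          !any(vapply(view$unaffected, function(u)
            hom_requirement(view, k, u, x_linked), logical(1)))
      }, logical(1))]
      if (length(cand) < 2) next
      # parental origin from genotype presence (no read-backed phasing)
      a1 <- chet_affected[1]
      par <- parents_of(view, a1)
      f <- par[["father"]]; m <- par[["mother"]]
      both_genotyped <- genotyped_any(view, cand, f) && genotyped_any(view, cand, m)
      if (!is.na(f) && !is.na(m) && both_genotyped) {
        pat <- cand[vapply(cand, function(k)
          carries(zyg_at(view, k, f)) && !carries(zyg_at(view, k, m)), logical(1))]
        mat <- cand[vapply(cand, function(k)
          carries(zyg_at(view, k, m)) && !carries(zyg_at(view, k, f)), logical(1))]
        if (!length(pat) || !length(mat)) next
        sel <- c(pat, mat)
        origin <- c(rep("paternal", length(pat)), rep("maternal", length(mat)))
      } else {
        sel <- cand
        origin <- rep("unknown", length(cand))
      }
      chet_genes[[length(chet_genes) + 1L]] <-
        list(gene = gene, keys = sel, origin = stats::setNames(origin, sel))
    }
  }
  list(hom_keys = keys[hom], chet_genes = chet_genes)
}

genotyped_any <- function(view, keys, ind) {
  !is.na(ind) && any(vapply(keys, function(k) genotyped(view, k, ind), logical(1)))
}

x_only_check <- function(view, x = TRUE) {
  on_x <- view$chrom[view_keys(view)] %in% c("X", "x")
  if (x && any(!on_x))
    stop("autosomal key passed to an X-linked filter: ",
         view_keys(view)[!on_x][1])
  invisible(TRUE)
}

#' Restrict a view to X-chromosome (or autosomal) keys
#' @param view A `family_view`.
#' @param x Keep X keys (TRUE) or autosomal keys (FALSE).
#' @return The restricted view.
#' @export
restrict_view <- function(view, x = TRUE) {
  on_x <- view$chrom[view_keys(view)] %in% c("X", "x")
  keep <- if (x) on_x else !on_x
  view$zyg <- view$zyg[keep, , drop = FALSE]
  view$chrom <- view$chrom[keep]
  view$genes <- view$genes[keep]
  view
}

#' X-linked dominant filter
#'
#' The autosomal dominant rules applied to X-chromosome keys, with
#' hemizygous male handling: any alt-carrying male call counts as carrying.
#'
#' @param view A `family_view` restricted to X keys (see [restrict_view()]).
#' @param de_novo,incomplete_penetrance As in [filter_autosomal_dominant()].
#' @return Character vector of surviving keys.
#' @export
filter_x_dominant <- function(view, de_novo = FALSE, incomplete_penetrance = FALSE) {
  x_only_check(view)
  # the dominant rules only ask "carries or not", under which HET-coded and
  # HOM-coded male calls already behave identically
  filter_autosomal_dominant(view, de_novo = de_novo,
                            incomplete_penetrance = incomplete_penetrance)
}

#' X-linked recessive filter
#'
#' Affected males are hemizygous: a single alt-carrying X call satisfies the
#' recessive requirement (treated as homozygous) and males are exempt from
#' compound-heterozygosity pairing. Affected females follow the full
#' recessive logic (HOM or C-HET). An unaffected male carrying a candidate
#' allele eliminates it — a hemizygous carrier male must be affected.
#'
#' @param view A `family_view` restricted to X keys.
#' @return As [filter_autosomal_recessive()].
#' @export
filter_x_recessive <- function(view) {
  x_only_check(view)
  bad <- view$affected[vapply(view$affected, function(a) sex_of(view, a) == "unknown",
                              logical(1))]
  if (length(bad))
    stop("X-linked recessive filtering needs known sex for affected individuals: ",
         paste(bad, collapse = ", "))
  filter_autosomal_recessive(view, x_linked = TRUE)
}

#' Mosaic allele-fraction filter
#'
#' Post-zygotic mutations present in a fraction of cells show sub-
#' heterozygous alternate-allele fractions. Per scoped sample the fraction
#' `f = alt / (ref + alt)` is computed from allele depths; a variant is kept
#' when `min_af <= f <= max_af` (closed interval) in at least one scoped
#' sample.
#'
#' @param vcf A `vcf_file` with AD fields.
#' @param min_af,max_af Window bounds, defaults 0.10-0.35 (the typical
#'   mosaic range).
#' @param samples Samples to scope (default: all samples in the file).
#' @return The filtered `vcf_file`.
#' @export
filter_mosaic <- function(vcf, min_af = 0.10, max_af = 0.35, samples = NULL) {
  stopifnot(min_af >= 0, min_af < max_af, max_af <= 1)
  if (is.null(samples)) samples <- vcf$samples
  any_depth <- any(vapply(vcf$variants, function(v)
    any(vapply(samples, function(s) {
      cl <- v$calls[[s]]
      !is.null(cl) && !is.null(cl$allele_depths) && !anyNA(cl$allele_depths)
    }, logical(1))), logical(1)))
  if (length(vcf$variants) && !any_depth)
    stop("mosaic filtering needs per-allele read depths (AD) for the scoped samples")
  keep <- vapply(vcf$variants, function(v) {
    any(vapply(samples, function(s) {
      cl <- v$calls[[s]]
      if (is.null(cl) || is.null(cl$allele_depths) || anyNA(cl$allele_depths)) return(FALSE)
      tot <- sum(cl$allele_depths)
      if (tot == 0) return(FALSE)
      f <- sum(cl$allele_depths[-1]) / tot
      f >= min_af && f <= max_af
    }, logical(1)))
  }, logical(1))
  subset_variants(vcf, keep)
}

#' Apply an inheritance model across a family's VCFs
#'
#' Builds the family genotype view, runs the requested trait-penetrance
#' filter and subsets every individual's VCF to the surviving keys, tagging
#' survivors with the model name (and, for compound heterozygotes, the gene
#' and partner keys) in-line.
#'
#' @param vcfs Named list of `vcf_file`s (names = individual ids).
#' @param ped A `pedigree`.
#' @param model One of "AD", "AD_denovo", "AR", "XLD", "XLR", "mosaic".
#' @param mosaic_window `c(min_af, max_af)` for the mosaic model.
#' @return A list: `vcfs` (filtered, tagged), `keys` (surviving keys),
#'   `chet_genes` (recessive models only).
#' @export
apply_inheritance <- function(vcfs, ped, model, mosaic_window = c(0.10, 0.35)) {
  model <- match.arg(model, c("AD", "AD_denovo", "AR", "XLD", "XLR", "mosaic"))
  if (model == "mosaic") {
    affected <- ped$individual_id[ped$affected == "affected"]
    out <- lapply(names(vcfs), function(ind) {
      if (!ind %in% affected) return(subset_variants(vcfs[[ind]], logical(n_variants(vcfs[[ind]]))))
      filter_mosaic(vcfs[[ind]], mosaic_window[1], mosaic_window[2])
    })
    names(out) <- names(vcfs)
    keys <- unique(unlist(lapply(out, function(vcf)
      vapply(vcf$variants, variant_key, character(1)))))
    out <- lapply(out, tag_model, model = "mosaic", chet = NULL)
    return(list(vcfs = out, keys = keys, chet_genes = list()))
  }
  view <- family_genotype_view(ped, vcfs)
  chet <- list()
  if (model %in% c("AD", "AD_denovo")) {
    view <- restrict_view(view, x = FALSE)
    keys <- filter_autosomal_dominant(view, de_novo = (model == "AD_denovo"))
  } else if (model == "AR") {
    view <- restrict_view(view, x = FALSE)
    res <- filter_autosomal_recessive(view)
    keys <- unique(c(res$hom_keys, unlist(lapply(res$chet_genes, `[[`, "keys"))))
    chet <- res$chet_genes
  } else if (model == "XLD") {
    view <- restrict_view(view, x = TRUE)
    keys <- filter_x_dominant(view)
  } else {
    view <- restrict_view(view, x = TRUE)
    res <- filter_x_recessive(view)
    keys <- unique(c(res$hom_keys, unlist(lapply(res$chet_genes, `[[`, "keys"))))
    chet <- res$chet_genes
  }
  out <- lapply(vcfs, function(vcf) {
    k <- vapply(vcf$variants, variant_key, character(1))
    tag_model(subset_variants(vcf, k %in% keys), model = model, chet = chet)
  })
  list(vcfs = out, keys = keys, chet_genes = chet)
}

tag_model <- function(vcf, model, chet) {
  chet_by_key <- list()
  for (cg in chet) {
    for (k in cg$keys) {
      partners <- setdiff(cg$keys, k)
      chet_by_key[[k]] <- sprintf("%s:%s", cg$gene, paste(partners, collapse = "+"))
    }
  }
  vcf$variants <- lapply(vcf$variants, function(v) {
    v$model <- model
    k <- variant_key(v)
    if (!is.null(chet_by_key[[k]])) v$chet <- chet_by_key[[k]]
    v
  })
  vcf
}
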