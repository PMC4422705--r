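#' Generate a synthetic protein-complex catalog with known composition
#'
#' Emits a catalog in the curated-complex layout (complex id, name,
#' semicolon-separated subunits) over a gene universe with known
#' expression classes, plus a truth table giving each complex's planted
#' composition. Deliberate homo-oligomers (a single distinct subunit)
#' and fully-non-expressed complexes (all subunits outside the
#' universe) are included so the catalog filters are exercised; when
#' `n_complexes >= 20` at least one of each is guaranteed.
#'
#' @param gene_classes data.frame with columns `gene` and `class`
#'   (`non_dynamic`, `dynamic`, `super_dynamic`, `unresolved`); the
#'   expressed gene universe.
#' @param n_complexes number of catalog entries.
#' @param size_range integer length-2: min/max distinct subunits per
#'   ordinary complex.
#' @param class_mix named numeric, proportions over planted composition
#'   classes `all_non_dynamic`, `all_dynamic`, `di_chromatic`,
#'   `contains_unresolved` (normalized internally).
#' @param homo_rate,non_expressed_rate fractions of entries planted as
#'   homo-oligomers / fully-non-expressed.
#' @param seed integer seed.
#' @return list with:
#'   \item{catalog}{data.frame: complex_id, name, subunits (";"-sep).}
#'   \item{truth}{data.frame: complex_id, planted (composition class or
#'     `homo_oligomer` / `fully_non_expressed`).}
#' @export
synth_complex_catalog <- function(gene_classes, n_complexes = 50,
                                  size_range = c(2, 10),
                                  class_mix = c(all_non_dynamic = 0.19,
                                                all_dynamic = 0.26,
                                                di_chromatic = 0.55,
                                                contains_unresolved = 0),
                                  homo_rate = 0.08,
                                  non_expressed_rate = 0.08,
                                  seed = 1L) {
  if (nrow(gene_classes) == 0) stop("empty gene universe")
  if (max(size_range) >= nrow(gene_classes)) {
    stop("size_range max must be smaller than the gene universe")
  }
  mix_names <- c("all_non_dynamic", "all_dynamic", "di_chromatic",
                 "contains_unresolved")
  class_mix <- class_mix[mix_names]
  class_mix[is.na(class_mix)] <- 0
  if (sum(class_mix) <= 0) stop("class_mix must have positive mass")
  class_mix <- class_mix / sum(class_mix)

  by_class <- split(gene_classes$gene, gene_classes$class)
  dyn_pool <- c(by_class$dynamic, by_class$super_dynamic)
  nd_pool <- by_class$non_dynamic
  unres_pool <- by_class$unresolved

  local_seed(seed, {
    n_homo <- round(n_complexes * homo_rate)
    n_nx <- round(n_complexes * non_expressed_rate)
    if (n_complexes >= 20) {
      n_homo <- max(n_homo, 1L)
      n_nx <- max(n_nx, 1L)
    }
    n_ord <- n_complexes - n_homo - n_nx
    if (n_ord < 0) stop("homo_rate + non_expressed_rate too large")
    planted_ord <- sample(mix_names, n_ord, replace = TRUE,
                          prob = class_mix)

    draw <- function(pool, k) sample(pool, k)
    make_members <- function(cls, size) {
      switch(cls,
        all_non_dynamic = draw(nd_pool, size),
        all_dynamic = draw(dyn_pool, size),
        di_chromatic = {
          k_dyn <- sample(seq_len(size - 1L), 1L)
          c(draw(dyn_pool, k_dyn), draw(nd_pool, size - k_dyn))
        },
        contains_unresolved = {
          if (length(unres_pool) == 0) {
            stop("class_mix requests unresolved members but the gene ",
                 "universe has none")
          }
          k_u <- sample(seq_len(size - 1L), 1L)
          c(draw(unres_pool, min(k_u, length(unres_pool))),
            draw(c(nd_pool, dyn_pool), size - min(k_u, length(unres_pool))))
        })
    }

    subunits <- character(n_complexes)
    planted <- character(n_complexes)
    i <- 0L
    for (j in seq_len(n_ord)) {
      i <- i + 1L
      size <- sample(size_range[1]:size_range[2], 1L)
      subunits[i] <- paste(make_members(planted_ord[j], size),
                           collapse = ";")
      planted[i] <- planted_ord[j]
    }
    for (j in seq_len(n_homo)) {
      i <- i + 1L
      g <- sample(gene_classes$gene, 1L)
      subunits[i] <- paste(rep(g, sample(2:4, 1L)), collapse = ";")
      planted[i] <- "homo_oligomer"
    }
    for (j in seq_len(n_nx)) {
      i <- i + 1L
      size <- sample(size_range[1]:size_range[2], 1L)
      subunits[i] <- paste(sprintf("NX%05d", sample(99999, size)),
                           collapse = ";")
      planted[i] <- "fully_non_expressed"
    }

    ord <- sample(n_complexes)   # shuffle so planted classes are interleaved
    complex_id <- sprintf("CPX%04d", seq_len(n_complexes))
    list(
      catalog = data.frame(complex_id = complex_id,
                           name = paste0("synthetic complex ", complex_id),
                           subunits = subunits[ord]),
      truth = data.frame(complex_id = complex_id, planted = planted[ord])
    )
  })
}
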