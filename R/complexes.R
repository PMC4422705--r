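#' Load a curated-complex catalog from a tab-delimited file
#'
#' Expects three tab-separated columns per line: complex id, name, and
#' a `";"`-separated subunit gene list (a header line is detected and
#' skipped). Duplicate subunit ids within a complex are collapsed to
#' the distinct set with the original record count retained; complexes
#' reduced to a single distinct subunit are flagged homo-oligomers.
#'
#' @param path file path, or a data.frame with columns `complex_id`,
#'   `name`, `subunits` (";"-separated).
#' @return data.frame: complex_id, name, subunits (";"-sep distinct),
#'   size (distinct subunits), n_records (pre-collapse),
#'   homo_oligomer (logical).
#' @export
load_complex_catalog <- function(path) {
  if (is.data.frame(path)) {
    df <- path
    stopifnot(all(c("complex_id", "name", "subunits") %in% names(df)))
  } else {
    lines <- readLines(path)
    if (length(lines) && grepl("^complex_id\t", lines[1])) {
      lines <- lines[-1]
    }
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, 1L) != 3L)
    if (length(bad)) {
      stop("malformed catalog line(s): ", paste(head(bad, 5),
                                                collapse = ", "))
    }
    df <- data.frame(complex_id = vapply(parts, `[`, "", 1L),
                     name = vapply(parts, `[`, "", 2L),
                     subunits = vapply(parts, `[`, "", 3L))
  }
  subs <- strsplit(df$subunits, ";", fixed = TRUE)
  empty <- vapply(subs, function(s) length(s) == 0 || any(!nzchar(s)),
                  TRUE)
  if (any(empty)) {
    stop("empty subunit field in complex(es): ",
         paste(head(df$complex_id[empty], 5), collapse = ", "))
  }
  distinct <- lapply(subs, unique)
  data.frame(
    complex_id = df$complex_id,
    name = df$name,
    subunits = vapply(distinct, paste, "", collapse = ";"),
    size = vapply(distinct, length, 1L),
    n_records = vapply(subs, length, 1L),
    homo_oligomer = vapply(distinct, length, 1L) == 1L
  )
}

#' Filter a complex catalog against the expressed gene universe
#'
#' Drops homo-oligomers and complexes with no expressed subunit; flags
#' partially-non-expressed complexes; optionally excludes complexes at
#' or above a size limit (the structural stage uses `size_limit = 20`,
#' i.e. keeps complexes with fewer than 20 distinct members).
#'
#' @param catalog data.frame from [load_complex_catalog()].
#' @param expressed character vector of expressed gene ids.
#' @param size_limit optional integer; complexes with
#'   `size >= size_limit` are dropped.
#' @return list: `catalog` (survivors, with `partially_non_expressed`
#'   flag), `report` list(n_input, n_homo_oligomer,
#'   n_fully_non_expressed, n_size_excluded, n_survivors).
#' @export
filter_complex_catalog <- function(catalog, expressed,
                                   size_limit = NULL) {
  if (length(expressed) == 0) stop("expressed gene set is empty")
  subs <- strsplit(catalog$subunits, ";", fixed = TRUE)
  n_expr <- vapply(subs, function(s) sum(s %in% expressed), 1L)
  homo <- catalog$homo_oligomer
  fully_nx <- !homo & n_expr == 0
  over <- if (is.null(size_limit)) rep(FALSE, nrow(catalog)) else
    catalog$size >= size_limit
  size_ex <- !homo & !fully_nx & over
  keep <- !homo & !fully_nx & !size_ex
  out <- catalog[keep, , drop = FALSE]
  out$partially_non_expressed <-
    vapply(subs[keep], function(s) any(!(s %in% expressed)), TRUE)
  rownames(out) <- NULL
  list(catalog = out,
       report = list(n_input = nrow(catalog),
                     n_homo_oligomer = sum(homo),
                     n_fully_non_expressed = sum(fully_nx),
                     n_size_excluded = sum(size_ex),
                     n_survivors = nrow(out)))
}

#' Composition class of a complex from its members' expression classes
#'
#' In `"exclude_unresolved"` mode, complexes containing any unresolved
#' member are set aside (`NA`); the remainder are `all_non_dynamic`,
#' `all_dynamic` (dynamic and super-dynamic pooled), or `di_chromatic`
#' (a mix). In `"unresolved_as_nondynamic"` mode unresolved members
#' count as non-dynamic.
#'
#' @param member_classes character vector of per-subunit classes.
#' @param mode `"exclude_unresolved"` or `"unresolved_as_nondynamic"`.
#' @return composition label, or NA (set aside).
#' @export
classify_composition <- function(member_classes,
                                 mode = c("exclude_unresolved",
                                          "unresolved_as_nondynamic")) {
  mode <- match.arg(mode)
  known <- c("non_dynamic", "dynamic", "super_dynamic", "unresolved")
  if (!all(member_classes %in% known)) {
    stop("unknown expression class: ",
         paste(setdiff(member_classes, known), collapse = ", "))
  }
  if (mode == "exclude_unresolved" && any(member_classes == "unresolved")) {
    return(NA_character_)
  }
  dyn <- member_classes %in% c("dynamic", "super_dynamic")
  if (all(dyn)) "all_dynamic"
  else if (all(!dyn)) "all_non_dynamic"
  else "di_chromatic"
}

#' Classify every complex in a filtered catalog
#'
#' @param catalog filtered catalog (see [filter_complex_catalog()]).
#' @param classes data.frame `gene`, `class`; subunits absent from the
#'   table are treated as unresolved.
#' @param mode see [classify_composition()].
#' @return catalog with added `composition` column (NA = set aside).
#' @export
classify_complexes <- function(catalog, classes,
                               mode = c("exclude_unresolved",
                                        "unresolved_as_nondynamic")) {
  mode <- match.arg(mode)
  cls <- setNames(classes$class, classes$gene)
  subs <- strsplit(catalog$subunits, ";", fixed = TRUE)
  catalog$composition <- vapply(subs, function(s) {
    mc <- unname(cls[s])
    mc[is.na(mc)] <- "unresolved"
    classify_composition(mc, mode)
  }, character(1))
  catalog
}

#' Composition distribution over classifiable complexes
#'
#' @param catalog classified catalog from [classify_complexes()].
#' @return data.frame: composition, n, fraction (sums to 1),
#'   percent (integer-rounded).
#' @export
composition_distribution <- function(catalog) {
  comp <- catalog$composition[!is.na(catalog$composition)]
  if (length(comp) == 0) stop("no classifiable complexes")
  levs <- c("all_non_dynamic", "all_dynamic", "di_chromatic")
  n <- as.integer(table(factor(comp, levels = levs)))
  data.frame(composition = levs, n = n, fraction = n / sum(n),
             percent = round(100 * n / sum(n)))
}

#' Permutation test of subunit co-regulation within a complex
#'
#' Statistic: mean pairwise Pearson correlation among the expressed
#' subunits' time-point mean profiles. Null: the same statistic for
#' random same-size gene sets drawn from the expressed universe.
#' p = (1 + #\{null >= observed\}) / (n_permutations + 1).
#'
#' @param members subunit gene ids.
#' @param mat gene-level log2 matrix, columns `"t<i>_r<j>"`.
#' @param n_permutations number of null draws (default 999).
#' @param seed integer seed.
#' @return list(statistic, p, n_members) or list(skipped = TRUE) when
#'   fewer than 2 subunits are expressed.
#' @export
coregulation_test <- function(members, mat, n_permutations = 999,
                              seed = 1L) {
  tm <- timepoint_means(mat)
  members <- intersect(members, rownames(tm))
  if (length(members) < 2) return(list(skipped = TRUE))
  mean_pcc <- function(g) {
    cm <- cor(t(tm[g, , drop = FALSE]))
    mean(cm[upper.tri(cm)])
  }
  obs <- mean_pcc(members)
  local_seed(seed, {
    null <- vapply(seq_len(n_permutations), function(i) {
      mean_pcc(sample(rownames(tm), length(members)))
    }, numeric(1))
    list(statistic = obs,
         p = (1 + sum(null >= obs)) / (n_permutations + 1),
         n_members = length(members), skipped = FALSE)
  })
}

#' Export node and edge tables for graph viewers
#'
#' @param catalog classified catalog (subunits `";"`-separated).
#' @param classes data.frame `gene`, `class`.
#' @param assignments optional named vector gene -> cluster id.
#' @param fold_changes optional named vector gene -> linear fold change.
#' @return list: `nodes` (gene, class, cluster, abs_log2_fold),
#'   `edges` (geneA, geneB, complex_id).
#' @export
export_network <- function(catalog, classes, assignments = NULL,
                           fold_changes = NULL) {
  subs <- strsplit(catalog$subunits, ";", fixed = TRUE)
  edges <- do.call(rbind, lapply(seq_along(subs), function(i) {
    s <- subs[[i]]
    if (length(s) < 2) return(NULL)
    pr <- t(combn(sort(s), 2L))
    data.frame(geneA = pr[, 1], geneB = pr[, 2],
               complex_id = catalog$complex_id[i])
  }))
  if (is.null(edges)) {
    edges <- data.frame(geneA = character(0), geneB = character(0),
                        complex_id = character(0))
  }
  genes <- sort(unique(unlist(subs))) %||% character(0)
  cls <- setNames(classes$class, classes$gene)
  nodes <- data.frame(
    gene = genes,
    class = unname(ifelse(is.na(cls[genes]), "unresolved",
                          cls[genes])),
    cluster = if (is.null(assignments)) rep(NA_integer_, length(genes))
      else unname(assignments[genes]),
    abs_log2_fold = if (is.null(fold_changes))
      rep(NA_real_, length(genes)) else
      abs(log2(unname(fold_changes[genes])))
  )
  rownames(nodes) <- NULL
  list(nodes = nodes, edges = edges)
}
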