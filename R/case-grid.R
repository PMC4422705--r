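# Expression-by-compatibility case grid. Classes collapse to three
# levels (dynamic pools dynamic + super_dynamic), giving 3 hub classes
# x 6 unordered partner-pair classes = 18 cases. The first three case
# ids are fixed by their biological reading: case 1 = non-dynamic hub
# with two dynamic partners (competition at a stable core), case 2 =
# all three dynamic, case 3 = all three non-dynamic. Remaining cases
# are numbered 4..18 scanning hubs (non_dynamic, dynamic, unresolved)
# by pairs (DD, NN, UU, DN, DU, NU).

collapse3 <- function(x) {
  known <- c("non_dynamic", "dynamic", "super_dynamic", "unresolved")
  if (!all(x %in% known)) {
    stop("unknown expression class: ",
         paste(unique(setdiff(x, known)), collapse = ", "))
  }
  ifelse(x == "super_dynamic", "dynamic", x)
}

pair_key <- function(a, b) {
  ab <- rbind(pmin(a, b), pmax(a, b))
  paste(ab[1, ], ab[2, ], sep = "+")
}

case_layout <- function() {
  hubs <- c("non_dynamic", "dynamic", "unresolved")
  singles <- c("dynamic", "non_dynamic", "unresolved")
  pairs <- c("dynamic+dynamic", "non_dynamic+non_dynamic",
             "unresolved+unresolved", "dynamic+non_dynamic",
             "dynamic+unresolved", "non_dynamic+unresolved")
  pairs <- vapply(strsplit(pairs, "+", fixed = TRUE),
                  function(x) paste(sort(x), collapse = "+"), "")
  grid <- expand.grid(pair = pairs, hub = hubs,
                      stringsAsFactors = FALSE)[, c("hub", "pair")]
  fixed <- data.frame(
    hub = c("non_dynamic", "dynamic", "non_dynamic"),
    pair = c(pair_key("dynamic", "dynamic"),
             pair_key("dynamic", "dynamic"),
             pair_key("non_dynamic", "non_dynamic")))
  key <- function(df) paste(df$hub, df$pair, sep = "|")
  rest <- grid[!(key(grid) %in% key(fixed)), ]
  out <- rbind(fixed, rest)
  out$case <- seq_len(nrow(out))
  stopifnot(nrow(out) == 18L)
  out
}

#' Case id of a hub/partner-pair expression-class combination
#'
#' @param hub_class,classA,classB expression class labels (dynamic and
#'   super_dynamic pool to "dynamic").
#' @return integer case ids in 1..18 (see [case_grid()] for layout).
#' @export
triplet_case <- function(hub_class, classA, classB) {
  layout <- case_layout()
  key <- paste(collapse3(hub_class),
               pair_key(collapse3(classA), collapse3(classB)),
               sep = "|")
  layout$case[match(key, paste(layout$hub, layout$pair, sep = "|"))]
}

#' Tabulate AND/XOR calls over the 18-case expression grid
#'
#' @param calls data.frame with columns `hub_class`, `classA`,
#'   `classB`, `call` (`"AND"`/`"XOR"`) — e.g. from
#'   [enumerate_triplets()].
#' @return data.frame: case, hub_class, partner_pair, n_xor, n_and,
#'   frac_xor, frac_and (raw), pct_xor, pct_and (integer-rounded).
#' @export
case_grid <- function(calls) {
  stopifnot(all(calls$call %in% c("AND", "XOR")))
  layout <- case_layout()
  case <- triplet_case(calls$hub_class, calls$classA, calls$classB)
  n_xor <- vapply(layout$case, function(cc)
    sum(case == cc & calls$call == "XOR"), 1L)
  n_and <- vapply(layout$case, function(cc)
    sum(case == cc & calls$call == "AND"), 1L)
  tot <- n_xor + n_and
  data.frame(case = layout$case, hub_class = layout$hub,
             partner_pair = layout$pair, n_xor = n_xor, n_and = n_and,
             frac_xor = ifelse(tot > 0, n_xor / tot, NA_real_),
             frac_and = ifelse(tot > 0, n_and / tot, NA_real_),
             pct_xor = as.integer(ifelse(tot > 0,
                                         round(100 * n_xor / tot), NA)),
             pct_and = as.integer(ifelse(tot > 0,
                                         round(100 * n_and / tot), NA)))
}

#' Per-case Fisher enrichment of XOR vs AND with Bonferroni correction
#'
#' For each populated case, tests the 2x2 table \[case XOR, case AND;
#' pooled-other XOR, pooled-other AND\] with a two-sided Fisher exact
#' test; q = min(1, m * p) with m the number of populated cases. The
#' case-versus-pooled-remainder table construction is this package's
#' interpretation and can be switched to pairwise case-vs-case via
#' `against`.
#'
#' @param grid output of [case_grid()].
#' @param against `"pooled"` (default) or an integer case id to
#'   compare every case to.
#' @return data.frame: case, n_xor, n_and, odds_ratio, p, q,
#'   degenerate (zero-margin tables get p = 1 and a flag).
#' @export
enrichment_test <- function(grid, against = "pooled") {
  pop <- grid[grid$n_xor + grid$n_and > 0, , drop = FALSE]
  if (nrow(pop) < 2) stop("need >= 2 populated cases")
  m <- nrow(pop)
  res <- lapply(seq_len(nrow(pop)), function(i) {
    if (identical(against, "pooled")) {
      ox <- sum(pop$n_xor[-i]); oa <- sum(pop$n_and[-i])
    } else {
      j <- which(pop$case == against)
      if (length(j) != 1) stop("reference case not populated")
      ox <- pop$n_xor[j]; oa <- pop$n_and[j]
    }
    tab <- matrix(c(pop$n_xor[i], pop$n_and[i], ox, oa), nrow = 2,
                  byrow = TRUE)
    degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
    if (degenerate) {
      data.frame(case = pop$case[i], n_xor = pop$n_xor[i],
                 n_and = pop$n_and[i], odds_ratio = NA_real_, p = 1,
                 degenerate = TRUE)
    } else {
      ft <- fisher.test(tab, alternative = "two.sided")
      data.frame(case = pop$case[i], n_xor = pop$n_xor[i],
                 n_and = pop$n_and[i],
                 odds_ratio = unname(ft$estimate), p = ft$p.value,
                 degenerate = FALSE)
    }
  })
  out <- do.call(rbind, res)
  out$q <- pmin(1, m * out$p)
  out
}

#' XOR hubs whose super-dynamic partners span multiple clusters
#'
#' Over hubs appearing in XOR calls, counts the distinct temporal
#' clusters among each hub's super-dynamic XOR partners. A hub
#' qualifies when it has >= 2 super-dynamic partners with cluster
#' assignments.
#'
#' @param calls triplet call table (see [enumerate_triplets()]).
#' @param classes data.frame `gene`, `class`.
#' @param assignments named vector gene -> cluster id.
#' @return list: `per_hub` data.frame (hub, n_super_partners,
#'   n_clusters), `n_qualifying`, `n_spanning` (hubs spanning >= 2
#'   clusters).
#' @export
xor_cluster_span <- function(calls, classes, assignments) {
  cls <- setNames(classes$class, classes$gene)
  xor <- calls[calls$call == "XOR", , drop = FALSE]
  per_hub <- lapply(unique(xor$hub), function(h) {
    partners <- unique(c(xor$partnerA[xor$hub == h],
                         xor$partnerB[xor$hub == h]))
    super <- partners[!is.na(cls[partners]) &
                        cls[partners] == "super_dynamic"]
    cl <- assignments[intersect(super, names(assignments))]
    cl <- cl[!is.na(cl)]
    data.frame(hub = h, n_super_partners = length(cl),
               n_clusters = length(unique(cl)))
  })
  per_hub <- if (length(per_hub)) do.call(rbind, per_hub) else
    data.frame(hub = character(0), n_super_partners = integer(0),
               n_clusters = integer(0))
  qual <- per_hub$n_super_partners >= 2
  list(per_hub = per_hub, n_qualifying = sum(qual),
       n_spanning = sum(qual & per_hub$n_clusters >= 2))
}
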