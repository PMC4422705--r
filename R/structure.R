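# Geometry engine: interface detection, rigid superposition, backbone
# clash counting, and AND/XOR compatibility calls for two partners
# sharing a hub domain.

domain_xyz <- function(dom) as.matrix(dom$atoms[, c("x", "y", "z")])

# squared cross-distances between two coordinate matrices
cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
}

#' Interface residues between two domains
#'
#' A residue belongs to the interface iff any of its backbone atoms
#' lies within `cutoff` of any backbone atom of the other domain.
#'
#' @param domA,domB `"domain_instance"` objects in a common frame.
#' @param cutoff distance cutoff in Angstrom (default 5.0).
#' @return list(residuesA, residuesB): sorted residue numbers.
#' @export
find_interface <- function(domA, domB, cutoff = 5.0) {
  d2 <- cross_dist2(domain_xyz(domA), domain_xyz(domB))
  close <- d2 <= cutoff^2
  list(residuesA = sort(unique(domA$atoms$resno[rowSums(close) > 0])),
       residuesB = sort(unique(domB$atoms$resno[colSums(close) > 0])))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD
#' between matched backbone atoms of two copies of the same domain
#' (matched by residue number and atom name), mapping the second
#' copy's frame onto the first's.
#'
#' @param domA,domB two `"domain_instance"` copies of one domain with
#'   identical residue numbering.
#' @return list(rotation, translation, rmsd): `x_new = x %*% t(rotation)
#'   + translation` maps frame-B coordinates into frame A; rmsd over
#'   matched atoms after superposition.
#' @export
superpose_domains <- function(domA, domB) {
  key <- function(d) paste(d$atoms$resno, d$atoms$elety)
  ia <- match(key(domB), key(domA))
  if (any(is.na(ia))) stop("domain copies must share residue numbering")
  A <- domain_xyz(domA)[ia, , drop = FALSE]
  B <- domain_xyz(domB)
  if (length(unique(domB$atoms$resno)) < 3) {
    stop("need >= 3 matched residues for superposition")
  }
  ca <- unname(colMeans(A)); cb <- unname(colMeans(B))
  H <- crossprod(sweep(B, 2, cb), sweep(A, 2, ca))
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- ca - as.vector(R %*% cb)
  Bfit <- B %*% t(R) + rep(tr, each = nrow(B))
  list(rotation = R, translation = tr,
       rmsd = sqrt(mean(rowSums((Bfit - A)^2))))
}

#' Backbone clash fraction between two placed partners
#'
#' With both partners in the common hub frame and their hub-facing
#' interface residues precomputed, an interface residue clashes iff
#' any of its backbone atoms lies within `clash_cutoff` of any
#' backbone atom of the other partner. The fraction is the number of
#' clashing interface residues over the union interface size (both
#' partners pooled).
#'
#' @param partnerA,partnerB `"domain_instance"`s in the hub frame.
#' @param interfaceA,interfaceB residue numbers of each partner's hub
#'   interface.
#' @param clash_cutoff Angstrom (default 2.5).
#' @return fraction in \[0, 1\], or NA when the union interface is
#'   empty (triplet should be skipped).
#' @export
clash_fraction <- function(partnerA, partnerB, interfaceA, interfaceB,
                           clash_cutoff = 2.5) {
  n_union <- length(interfaceA) + length(interfaceB)
  if (n_union == 0) return(NA_real_)
  d2 <- cross_dist2(domain_xyz(partnerA), domain_xyz(partnerB))
  close <- d2 <= clash_cutoff^2
  clashA <- unique(partnerA$atoms$resno[rowSums(close) > 0])
  clashB <- unique(partnerB$atoms$resno[colSums(close) > 0])
  (sum(interfaceA %in% clashA) + sum(interfaceB %in% clashB)) / n_union
}

#' AND/XOR compatibility call from a clash fraction
#'
#' XOR (mutually exclusive) iff the clash fraction reaches the
#' threshold; the boundary is inclusive.
#'
#' @param fraction clash fraction in \[0, 1\].
#' @param threshold clash-fraction threshold (default 0.15).
#' @return `"XOR"` or `"AND"` (NA in, NA out).
#' @export
call_compatibility <- function(fraction, threshold = 0.15) {
  ifelse(is.na(fraction), NA_character_,
         ifelse(fraction >= threshold, "XOR", "AND"))
}

#' Call compatibility for one hub + two-partner triplet
#'
#' Superposes the two models' hub copies, places partner B into the
#' hub frame of model A, finds each partner's interface with the hub,
#' counts backbone clashes between the partners, and calls AND/XOR.
#'
#' @param modelA,modelB each a list(hub, partner) of
#'   `"domain_instance"`s (each model in its own frame).
#' @param interface_cutoff interface distance cutoff, Angstrom.
#' @param clash_cutoff clash distance cutoff, Angstrom.
#' @param threshold clash-fraction call threshold.
#' @return list(rmsd, clash_fraction, call, n_interfaceA,
#'   n_interfaceB, skipped).
#' @export
call_triplet <- function(modelA, modelB, interface_cutoff = 5.0,
                         clash_cutoff = 2.5, threshold = 0.15) {
  fit <- superpose_domains(modelA$hub, modelB$hub)
  partnerB <- transform_domain(modelB$partner, fit$rotation,
                               fit$translation)
  intA <- find_interface(modelA$partner, modelA$hub, interface_cutoff)
  intB <- find_interface(partnerB, modelA$hub, interface_cutoff)
  frac <- clash_fraction(modelA$partner, partnerB,
                         intA$residuesA, intB$residuesA, clash_cutoff)
  list(rmsd = fit$rmsd, clash_fraction = frac,
       call = call_compatibility(frac, threshold),
       n_interfaceA = length(intA$residuesA),
       n_interfaceB = length(intB$residuesA),
       skipped = is.na(frac))
}

#' Enumerate and call all hub triplets of modeled interactions
#'
#' Interaction models are pairwise structural models within complexes:
#' each carries a complex id, a hub protein, a partner protein, and
#' the hub/partner domain instances in the model's frame. For every
#' hub with at least two modeled partners within a complex, every
#' unordered partner pair is called; pairings of a hub with itself
#' (homo-oligomeric) are excluded, and models not flagged `accepted`
#' (template rejected) are skipped and counted.
#'
#' @param models list of lists: complex_id, hub, partner, hub_dom,
#'   partner_dom, accepted (optional, default TRUE).
#' @param classes data.frame `gene`, `class`; proteins absent are
#'   unresolved.
#' @param interface_cutoff,clash_cutoff,threshold see
#'   [call_triplet()].
#' @return list: `calls` data.frame (complex_id, hub, partnerA,
#'   partnerB, hub_class, classA, classB, rmsd, clash_fraction, call,
#'   case), `n_skipped` (triplets without two accepted models or with
#'   an empty interface).
#' @export
enumerate_triplets <- function(models, classes, interface_cutoff = 5.0,
                               clash_cutoff = 2.5, threshold = 0.15) {
  cls <- setNames(classes$class, classes$gene)
  lookup <- function(g) {
    x <- unname(cls[g]); if (is.na(x)) "unresolved" else x
  }
  accepted <- vapply(models, function(m) isTRUE(m$accepted %||% TRUE),
                     TRUE)
  keys <- vapply(models, function(m) paste(m$complex_id, m$hub,
                                           sep = "\r"), "")
  rows <- list(); n_skipped <- 0L
  for (key in unique(keys)) {
    idx <- which(keys == key)
    idx <- idx[vapply(models[idx], function(m) m$partner != m$hub, TRUE)]
    if (length(idx) < 2) next
    for (pr in asplit(combn(idx, 2L), 2L)) {
      mA <- models[[pr[1]]]; mB <- models[[pr[2]]]
      if (!accepted[pr[1]] || !accepted[pr[2]]) {
        n_skipped <- n_skipped + 1L
        next
      }
      res <- call_triplet(list(hub = mA$hub_dom, partner = mA$partner_dom),
                          list(hub = mB$hub_dom, partner = mB$partner_dom),
                          interface_cutoff, clash_cutoff, threshold)
      if (res$skipped) {
        n_skipped <- n_skipped + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        complex_id = mA$complex_id, hub = mA$hub,
        partnerA = mA$partner, partnerB = mB$partner,
        hub_class = lookup(mA$hub), classA = lookup(mA$partner),
        classB = lookup(mB$partner), rmsd = res$rmsd,
        clash_fraction = res$clash_fraction, call = res$call)
    }
  }
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(complex_id = character(0), hub = character(0),
               partnerA = character(0), partnerB = character(0),
               hub_class = character(0), classA = character(0),
               classB = character(0), rmsd = numeric(0),
               clash_fraction = numeric(0), call = character(0))
  if (nrow(calls)) {
    calls$case <- triplet_case(calls$hub_class, calls$classA,
                               calls$classB)
  } else {
    calls$case <- integer(0)
  }
  list(calls = calls, n_skipped = n_skipped)
}
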