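#' Build an idealized helical backbone domain
#'
#' Synthetic helix-like backbone (N, CA, C, O per residue) used by the
#' toy structural fixtures. Not a real protein fold: geometry is an
#' idealized alpha-helical spiral with canonical-ish backbone offsets,
#' sufficient to exercise interface detection, superposition, and clash
#' counting.
#'
#' @param n_res number of residues (>= 3).
#' @param protein protein identifier.
#' @param domain_type domain type identifier.
#' @return object of class `"domain_instance"`: list(protein,
#'   domain_type, atoms = data.frame(resno, elety, x, y, z)).
#' @export
toy_helix_domain <- function(n_res, protein = "prot",
                             domain_type = "HelixDom") {
  stopifnot(n_res >= 3)
  i <- seq_len(n_res)
  theta <- (i - 1) * 100 * pi / 180
  rise <- 1.5
  ca <- cbind(2.3 * cos(theta), 2.3 * sin(theta), rise * (i - 1))
  nn <- cbind(1.6 * cos(theta - 0.7), 1.6 * sin(theta - 0.7),
              rise * (i - 1) - 0.6)
  cc <- cbind(1.8 * cos(theta + 0.6), 1.8 * sin(theta + 0.6),
              rise * (i - 1) + 0.6)
  oo <- cc + matrix(rep(c(0.4, 0.4, 1.1), each = n_res), ncol = 3)
  atoms <- data.frame(
    resno = rep(i, times = 4),
    elety = rep(c("N", "CA", "C", "O"), each = n_res),
    x = c(nn[, 1], ca[, 1], cc[, 1], oo[, 1]),
    y = c(nn[, 2], ca[, 2], cc[, 2], oo[, 2]),
    z = c(nn[, 3], ca[, 3], cc[, 3], oo[, 3])
  )
  atoms <- atoms[order(atoms$resno, match(atoms$elety,
                                          c("N", "CA", "C", "O"))), ]
  rownames(atoms) <- NULL
  structure(list(protein = protein, domain_type = domain_type,
                 atoms = atoms), class = "domain_instance")
}

#' Apply a rigid-body transform to a domain instance
#'
#' @param dom a `"domain_instance"`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric.
#' @return transformed `"domain_instance"`.
#' @export
transform_domain <- function(dom, rotation = diag(3),
                             translation = c(0, 0, 0)) {
  xyz <- as.matrix(dom$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation) + rep(translation, each = nrow(xyz))
  dom$atoms[, c("x", "y", "z")] <- xyz
  dom
}

# uniform random rotation matrix (quaternion method)
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

rot_z <- function(angle) {
  matrix(c(cos(angle), -sin(angle), 0,
           sin(angle), cos(angle), 0,
           0, 0, 1), nrow = 3, byrow = TRUE)
}

jitter_domain <- function(dom, sd) {
  if (sd <= 0) return(dom)
  n <- nrow(dom$atoms)
  dom$atoms[, c("x", "y", "z")] <- dom$atoms[, c("x", "y", "z")] +
    matrix(rnorm(3 * n, 0, sd), ncol = 3)
  dom
}

#' Generate a toy hub + two-partner structural triplet
#'
#' Builds two interaction models sharing a hub domain: model A holds
#' the hub with partner A docked on its +x face; model B holds a second
#' copy of the hub (in an arbitrary rotated/translated frame, with
#' optional coordinate jitter) with partner B. In `"overlapping"` mode
#' partner B occupies the same hub face as partner A, so after
#' superposition onto the common hub the partners collide (ground truth
#' XOR); in `"disjoint"` mode partner B sits on the opposite face, far
#' beyond the clash cutoff (ground truth AND).
#'
#' @param placement `"overlapping"` or `"disjoint"`.
#' @param n_hub_res,n_partner_res residue counts of hub and partners.
#' @param jitter_sd per-atom Gaussian jitter (Angstrom) applied to
#'   model B; values above 1 Angstrom are flagged as geometrically
#'   ambiguous in the truth metadata.
#' @param seed integer seed (frame randomization + jitter).
#' @return list with:
#'   \item{modelA,modelB}{each list(hub, partner) of
#'     `"domain_instance"`s; model B is in its own frame.}
#'   \item{expected_call}{`"XOR"` (overlapping) or `"AND"` (disjoint).}
#'   \item{ambiguous}{TRUE if jitter_sd makes the geometry unreliable.}
#'   \item{template_table}{toy domain-interaction template rows for the
#'     template-scoring stage.}
#' @export
synth_toy_triplet <- function(placement = c("disjoint", "overlapping"),
                              n_hub_res = 20, n_partner_res = 10,
                              jitter_sd = 0, seed = 1L) {
  placement <- match.arg(placement)
  local_seed(seed, {
    hub <- toy_helix_domain(n_hub_res, "hubP", "HubDom")
    partner <- toy_helix_domain(n_partner_res, "partA", "PartDom")
    # center partner along the hub axis, docked on the +x face
    zc <- (max(hub$atoms$z) - max(partner$atoms$z)) / 2
    partnerA <- transform_domain(partner, diag(3), c(7.5, 0, zc))
    partnerB0 <- if (placement == "overlapping") {
      pb <- transform_domain(partner, diag(3), c(7.5, 0, zc))
      pb$protein <- "partB"
      pb
    } else {
      pb <- transform_domain(partner, rot_z(pi), c(0, 0, 0))
      pb <- transform_domain(pb, diag(3), c(-7.5, 0, zc))
      pb$protein <- "partB"
      pb
    }
    # model B lives in an arbitrary rigid frame
    R <- random_rotation()
    tr <- runif(3, -20, 20)
    hubB <- transform_domain(hub, R, tr)
    partnerB <- transform_domain(partnerB0, R, tr)
    if (jitter_sd > 0) {
      hubB <- jitter_domain(hubB, jitter_sd)
      partnerB <- jitter_domain(partnerB, jitter_sd)
    }
    template_table <- data.frame(
      template_id = c("TPL_A", "TPL_B"),
      hub_domain = "HubDom",
      partner_domain = "PartDom",
      interface_seq = c("LIVLKAERAG", "LIVLKAERAG")
    )
    list(
      modelA = list(hub = hub, partner = partnerA),
      modelB = list(hub = hubB, partner = partnerB),
      expected_call = if (placement == "overlapping") "XOR" else "AND",
      ambiguous = jitter_sd > 1,
      template_table = template_table
    )
  })
}

#' Write / read a domain instance as PDB ATOM records
#'
#' Thin wrappers over [bio3d::write.pdb()] / [bio3d::read.pdb()]
#' carrying only backbone atoms.
#'
#' @param dom a `"domain_instance"`.
#' @param file path.
#' @return `read_domain_pdb` returns a `"domain_instance"` (protein and
#'   domain type taken from `protein`/`domain_type` arguments).
#' @export
write_domain_pdb <- function(dom, file) {
  a <- dom$atoms
  xyz <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  n <- nrow(a)
  bio3d::write.pdb(file = file, xyz = xyz, resno = a$resno,
                   elety = a$elety, resid = rep("ALA", n),
                   chain = rep("A", n))
  invisible(file)
}

#' @rdname write_domain_pdb
#' @param protein,domain_type identifiers to attach on read.
#' @export
read_domain_pdb <- function(file, protein = "prot",
                            domain_type = "dom") {
  pdb <- bio3d::read.pdb(file)
  sel <- pdb$atom$elety %in% c("N", "CA", "C", "O")
  a <- pdb$atom[sel, ]
  atoms <- data.frame(resno = a$resno, elety = a$elety,
                      x = a$x, y = a$y, z = a$z)
  atoms <- atoms[order(atoms$resno, match(atoms$elety,
                                          c("N", "CA", "C", "O"))), ]
  rownames(atoms) <- NULL
  structure(list(protein = protein, domain_type = domain_type,
                 atoms = atoms), class = "domain_instance")
}
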