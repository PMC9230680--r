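# Small linear surrogate for the ring/rod/wire frame.
#
# The full finite-element treatment of the fixator (meshed tibia, frictional
# contact at the wires, tied hinges) is out of scope; this module is an
# intentionally small linear model whose every behaviour has a closed-form or
# symmetry check. Rigid rings, axial-spring rods, pretensioned beam-string
# wires, small displacements.
#
# Degrees of freedom:
#   moving ring: uz (axial translation, mm), rx, ry (tilts, rad)
#   bone node:   uzb (axial translation of the wired bone segment)
#   rod feed nodes: q_i (axial motion of the actuated end of each rod)
# The base ring is fixed. Rod i is an axial spring k_i between q_i and the
# ring attachment point (x_i, y_i); wire j is a transverse spring between the
# ring plane at its bone-crossing point and the bone node; the bone is
# restrained by a gap spring (regenerate/sensor) to ground.

#' Transverse stiffness of a pretensioned Kirschner wire
#'
#' Midspan transverse stiffness of a simply supported wire of free length
#' `L` under axial pretension `T`, superposing the beam bending term and the
#' taut-string term: `k = 48 EI / L^3 + 4 T / L`. With `T = 0` this is the
#' classical simply-supported-beam midspan stiffness; with `EI = 0` the
#' taut-string stiffness.
#'
#' @param T pretension, N (>= 0).
#' @param L free length between ring anchorages, mm (> 0).
#' @param EI bending rigidity, N.mm^2 (>= 0).
#' @return transverse stiffness, N/mm.
#' @examples
#' wire_transverse_stiffness(T = 100, L = 100, EI = 0)   # 4 N/mm
#' @export
wire_transverse_stiffness <- function(T, L, EI) {
  if (!all(is.finite(c(T, L, EI)))) stop("inputs must be finite")
  if (any(L <= 0)) stop("wire free length 'L' must be > 0")
  if (any(T < 0)) stop("pretension 'T' must be >= 0")
  if (any(EI < 0)) stop("bending rigidity 'EI' must be >= 0")
  48 * EI / L^3 + 4 * T / L
}

#' Define a ring/rod/wire frame system
#'
#' @param rod_xy n_rods x 2 matrix of rod attachment positions in the ring
#'   plane, mm. Rows ordered adjustable rods first. Positions must lie
#'   within the ring.
#' @param rod_k axial stiffness EA/L per rod, N/mm (recycled).
#' @param wire_xy n_wires x 2 matrix of wire bone-crossing points, mm.
#' @param wire_k transverse stiffness per wire, N/mm (recycled); defaults to
#'   [wire_transverse_stiffness()] of a 2.5 mm steel wire spanning the ring
#'   at 1000 N pretension.
#' @param gap_k axial stiffness of the osteotomy restraint (regenerate or
#'   force sensor), N/mm.
#' @param ring_diameter ring diameter, mm (bounds the rod positions).
#' @return an object of class `"frame_system"`.
#' @export
frame_system <- function(rod_xy, rod_k, wire_xy, wire_k = NULL,
                         gap_k = 1000, ring_diameter = 190) {
  rod_xy <- as.matrix(rod_xy); wire_xy <- as.matrix(wire_xy)
  stopifnot(ncol(rod_xy) == 2, ncol(wire_xy) == 2, nrow(rod_xy) >= 1)
  if (is.null(wire_k)) {
    EI <- steel_wire_EI(2.5)
    wire_k <- wire_transverse_stiffness(T = 1000, L = ring_diameter, EI = EI)
  }
  rod_k <- rep_len(rod_k, nrow(rod_xy))
  wire_k <- rep_len(wire_k, nrow(wire_xy))
  if (any(c(rod_k, wire_k, gap_k) <= 0)) stop("stiffnesses must be > 0")
  if (any(sqrt(rowSums(rod_xy^2)) > ring_diameter / 2 + 1e-9))
    stop("rod positions must lie within the ring")
  structure(list(rod_xy = rod_xy, rod_k = rod_k,
                 wire_xy = wire_xy, wire_k = wire_k,
                 gap_k = gap_k, ring_diameter = ring_diameter),
            class = "frame_system")
}

# bending rigidity of a solid steel wire, N.mm^2 (E = 200 GPa)
steel_wire_EI <- function(diameter_mm, E = 200e3) {
  E * pi * diameter_mm^4 / 64
}

#' Default bench frame
#'
#' Four rods at 45/135/225/315 degrees on a 190 mm ring (adjustable pair on
#' the +y side, support pair on the -y side), two crossed wires spanning the
#' ring, and a stiff gap spring standing in for the osteotomy force sensor.
#' Each wire crosses the bone cortex twice, so its transverse stiffness is
#' split over two crossing points 10 mm either side of the ring centre
#' (wire along x crosses at `(0, +/-10)`, wire along y at `(+/-10, 0)`).
#'
#' @param rod_k rod axial stiffness, N/mm.
#' @param gap_k gap/sensor stiffness, N/mm.
#' @return a [frame_system()].
#' @export
default_frame_system <- function(rod_k = 3.77e4, gap_k = 1000) {
  r <- 190 / 2 / sqrt(2)
  kw <- wire_transverse_stiffness(T = 1000, L = 190, EI = steel_wire_EI(2.5))
  frame_system(
    rod_xy = rbind(c(r, r), c(-r, r),      # adjustable rods 1, 2
                   c(r, -r), c(-r, -r)),   # support rods 3, 4
    rod_k = rod_k,
    wire_xy = rbind(c(0, 10), c(0, -10), c(10, 0), c(-10, 0)),
    wire_k = kw / 2,
    gap_k = gap_k)
}

#' Solve the frame for rod forces and bone-end force
#'
#' Static small-displacement solve of the ring/rod/wire surrogate. Two load
#' modes:
#' \describe{
#' \item{`rod_loads`}{axial forces applied at the actuated end of each rod
#'   (the distraction actuation). Each rod then carries exactly its applied
#'   force; the ring tilts under asymmetric loads and the wires distribute
#'   the resultant into the bone.}
#' \item{`ring_disp`}{prescribed moving-ring displacement
#'   `c(uz, rx, ry)` (mm, rad, rad) with the rod feed ends held; rod forces
#'   follow from the ring motion at each attachment.}
#' }
#'
#' @param system a [frame_system()].
#' @param rod_loads numeric vector of per-rod applied axial forces, N.
#' @param ring_disp numeric length-3 prescribed ring displacement
#'   `c(uz, rx, ry)`.
#' @return a list with `rod_force` (N, per rod), `wire_force` (N, per wire),
#'   `bone_end_force` (N), `ring_disp` (solved or prescribed), `bone_disp`
#'   (mm), and `residual` (max equilibrium residual, N).
#' @examples
#' sys <- default_frame_system()
#' solve_frame(sys, rod_loads = c(75, 75, 75, 75))
#' @export
solve_frame <- function(system, rod_loads = NULL, ring_disp = NULL) {
  stopifnot(inherits(system, "frame_system"))
  if (is.null(rod_loads) == is.null(ring_disp))
    stop("supply exactly one of 'rod_loads' or 'ring_disp'")
  nr <- nrow(system$rod_xy)
  nw <- nrow(system$wire_xy)

  # ring-plane kinematics: axial motion of a ring point (x, y) under
  # (uz, rx, ry) is uz + rx * y - ry * x
  B_ring <- function(xy) cbind(1, xy[, 2], -xy[, 1])
  Br <- B_ring(system$rod_xy)    # nr x 3
  Bw <- B_ring(system$wire_xy)   # nw x 3

  if (!is.null(ring_disp)) {
    ring_disp <- as.numeric(ring_disp)
    stopifnot(length(ring_disp) == 3)
    # rods: feed ends held, extension = ring motion at attachment
    rod_ext <- as.numeric(Br %*% ring_disp)
    rod_force <- system$rod_k * rod_ext
    # bone node equilibrium: sum k_wj (ring_j - uzb) = gap_k * uzb
    kw <- system$wire_k
    uzb <- sum(kw * as.numeric(Bw %*% ring_disp)) / (sum(kw) + system$gap_k)
    wire_force <- kw * (as.numeric(Bw %*% ring_disp) - uzb)
    bone_end <- system$gap_k * uzb
    res <- abs(sum(wire_force) - bone_end)
    return(list(rod_force = rod_force, wire_force = wire_force,
                bone_end_force = bone_end, ring_disp = ring_disp,
                bone_disp = uzb, residual = res))
  }

  rod_loads <- rep_len(as.numeric(rod_loads), nr)
  # unknowns: u = (uz, rx, ry, uzb, q_1..q_nr)
  ndof <- 4 + nr
  K <- matrix(0, ndof, ndof)
  f <- numeric(ndof)
  # rod i: spring k_i between q_i and ring point; e_i = Br_i u_ring - q_i
  for (i in seq_len(nr)) {
    a <- c(Br[i, ], 0, rep(0, nr)); a[4 + i] <- -1
    K <- K + system$rod_k[i] * tcrossprod(a)
  }
  # wire j: spring between ring plane and bone node; e_j = Bw_j u_ring - uzb
  for (j in seq_len(nw)) {
    a <- c(Bw[j, ], -1, rep(0, nr))
    K <- K + system$wire_k[j] * tcrossprod(a)
  }
  # gap spring on the bone node
  K[4, 4] <- K[4, 4] + system$gap_k
  f[4 + seq_len(nr)] <- -rod_loads   # push the feed end toward the ring

  # non-dimensionalize the tilt DOFs (rad) by the ring radius so the rank
  # check is not dominated by lever-arm scaling
  r0 <- system$ring_diameter / 2
  S <- diag(c(1, 1 / r0, 1 / r0, rep(1, 1 + nr)))
  Ks <- S %*% K %*% S
  ev <- eigen(Ks, symmetric = TRUE)
  if (min(ev$values) < 1e-9 * max(ev$values)) {
    mode <- ev$vectors[, ndof]
    names(mode) <- c("uz", "rx", "ry", "uzb", paste0("q", seq_len(nr)))
    stop("singular frame system: unconstrained mode dominated by '",
         names(mode)[which.max(abs(mode))], "'")
  }
  u <- as.numeric(S %*% solve(Ks, as.numeric(S %*% f)))
  ring <- u[1:3]; uzb <- u[4]; q <- u[4 + seq_len(nr)]
  # rod force positive when the rod carries its applied axial load; the
  # wire/gap chain reacts it, so those spring tensions carry the opposite
  # sign internally and are reported on the load's sign convention
  rod_force <- system$rod_k * (as.numeric(Br %*% ring) - q)
  wire_force <- -system$wire_k * (as.numeric(Bw %*% ring) - uzb)
  bone_end <- -system$gap_k * uzb
  res <- max(abs(K %*% u - f))
  list(rod_force = rod_force, wire_force = wire_force,
       bone_end_force = bone_end, ring_disp = ring, bone_disp = uzb,
       residual = res)
}
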