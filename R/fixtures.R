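# Cylindrical constants per backbone atom type for an ideal alpha-helix,
# frozen from an internal-coordinate build with ideal helical torsions
# (phi -57.8, psi -47, omega 180). Offsets are relative to the CA of the same
# residue; phases and z offsets scale with the requested twist and rise.
# The carbonyl O keeps its 1.23 A bond and a 120.5 deg CA-C-O angle but is
# tilted outward rather than along the i..i+4 hydrogen bond, so an isolated
# ideal helix has no non-bonded atom pair under 3.2 A (the fixtures must be
# contact-clash-free by construction).
.HELIX_REF <- list(
  rise = 1.542446, twist = 98.85267,
  atoms = data.frame(
    elety = c("N", "CA", "C", "O"),
    r = c(1.5639, 2.2889, 1.6834, 2.3827),
    dphi = c(-26.7408, 0, 26.7928, 56.1985),  # degrees
    dz = c(-0.9134, 0, 1.0638, 0.9156)        # Angstrom
  )
)

#' Generate an ideal alpha-helix backbone
#'
#' Builds a full-backbone (N, CA, C, O) helix along +z with the given rise and
#' twist; the CA trace lies on a cylinder of radius ~2.29 A. Atom offsets come
#' from an ideal-torsion reference helix and are rescaled linearly for
#' non-default rise/twist.
#'
#' @param n Number of residues (>= 1).
#' @param rise Rise per residue, A (default 1.5).
#' @param twist Twist per residue, degrees (default 100).
#' @param phase Azimuthal phase of residue 1, degrees.
#' @param chain Chain id.
#' @param resno_start First residue number.
#' @return A [backbone()] (the chain C-terminal residue carries no O when
#'   `n == 1` it still does; O is placed from the same-residue frame).
#' @export
ideal_helix <- function(n, rise = 1.5, twist = 100, phase = 0,
                        chain = "A", resno_start = 1) {
  stopifnot(n >= 1, rise > 0)
  ref <- .HELIX_REF
  rows <- lapply(seq_len(n), function(i) {
    th0 <- (phase + (i - 1) * twist) * pi / 180
    th <- th0 + ref$atoms$dphi * (twist / ref$twist) * pi / 180
    z <- (i - 1) * rise + ref$atoms$dz * (rise / ref$rise)
    data.frame(chain = chain, resno = resno_start + i - 1,
               elety = ref$atoms$elety,
               x = ref$atoms$r * cos(th), y = ref$atoms$r * sin(th), z = z)
  })
  backbone(do.call(rbind, rows))
}

#' Specification of a synthetic helical-repeat scaffold
#'
#' Defines a deterministic, clash-free stand-in for a designed helical repeat
#' protein (DHR): tandem two-helix repeats of straight, antiparallel
#' alpha-helices joined by short loops, packed on a triangular lattice.
#'
#' @param n_repeats Number of two-helix repeats (>= 2).
#' @param helix_len Residues per helix (default 20).
#' @param loop_len Residues per connecting loop (default 3).
#' @param helix_rise Helix rise, A/res (default 1.5).
#' @param helix_twist Helix twist, deg/res (default 100).
#' @param pack_dist Distance between adjacent helix axes, A (default 10).
#' @param repeat_twist Rotation between consecutive repeats about the repeat
#'   propagation axis, degrees (default 0: a straight array).
#' @param seed Integer recorded in the spec (the build itself is
#'   deterministic).
#' @return List of class `repeat_spec`.
#' @export
repeat_spec <- function(n_repeats = 4, helix_len = 20, loop_len = 3,
                        helix_rise = 1.5, helix_twist = 100, pack_dist = 10,
                        repeat_twist = 0, seed = 1L) {
  stopifnot(n_repeats >= 2, helix_len >= 6, loop_len >= 0,
            helix_rise > 0, pack_dist > 0)
  structure(list(n_repeats = n_repeats, helices_per_repeat = 2L,
                 helix_len = helix_len, loop_len = loop_len,
                 helix_rise = helix_rise, helix_twist = helix_twist,
                 pack_dist = pack_dist, repeat_twist = repeat_twist,
                 seed = as.integer(seed)),
            class = "repeat_spec")
}

# geometric loop between two CA anchors: a CA path with minimal N/C/O
# placeholders (loops are placeholders, never scored). When the straight path
# would give impossibly short CA-CA virtual bonds the path is bulged into an
# arc along `bulge_dir` until consecutive CAs are >= 3.2 A apart.
.loop_atoms <- function(ca_from, ca_to, n_loop, chain, resno_start,
                        bulge_dir = c(0, 0, 1)) {
  if (n_loop == 0) return(NULL)
  f <- seq_len(n_loop) / (n_loop + 1)
  L <- sqrt(sum((ca_to - ca_from)^2))
  nseg <- n_loop + 1
  if (L / nseg >= 3.2) {
    # straight path already gives sane virtual bonds
    pts <- rbind(ca_from, outer(1 - f, ca_from) + outer(f, ca_to), ca_to)
  } else {
    # circular arc in the plane of the chord and bulge_dir: every sub-chord
    # has the same length, chosen as 3.5 A
    u <- (ca_to - ca_from) / L
    w <- bulge_dir - sum(bulge_dir * u) * u
    w <- w / sqrt(sum(w^2))
    sub <- function(theta) L / (2 * sin(theta / 2)) * 2 * sin(theta / (2 * nseg))
    theta <- stats::uniroot(function(th) sub(th) - 3.5,
                            c(1e-6, 2 * pi - 1e-6))$root
    R <- L / (2 * sin(theta / 2))
    center <- (ca_from + ca_to) / 2 - w * R * cos(theta / 2)
    vA <- ca_from - center; vB <- ca_to - center
    tt <- c(0, f, 1)
    pts <- t(vapply(tt, function(t)
      center + (sin((1 - t) * theta) * vA + sin(t * theta) * vB) / sin(theta),
      numeric(3)))
  }
  rows <- lapply(seq_len(n_loop), function(j) {
    ca <- pts[j + 1, ]
    step <- (pts[j + 2, ] - pts[j, ]) / 2
    sn <- sqrt(sum(step^2))
    perp <- pracma::cross(step / sn,
                          if (abs(step[3] / sn) < 0.9) c(0, 0, 1) else c(1, 0, 0))
    perp <- perp / sqrt(sum(perp^2))
    nn <- ca - 0.38 * step + 0.15 * sn * perp
    cc <- ca + 0.38 * step + 0.15 * sn * perp
    oo <- cc + 1.23 * perp
    data.frame(chain = chain, resno = resno_start + j - 1,
               elety = c("N", "CA", "C", "O"),
               x = c(nn[1], ca[1], cc[1], oo[1]),
               y = c(nn[2], ca[2], cc[2], oo[2]),
               z = c(nn[3], ca[3], cc[3], oo[3]))
  })
  do.call(rbind, rows)
}

#' Build a synthetic helical-repeat backbone
#'
#' Places antiparallel up-down helices by rigid transforms: helix 2k-1 runs +z
#' at lattice position (k-1) * pack_dist on the x axis, helix 2k runs -z offset
#' by half a repeat in x and `pack_dist * sqrt(3)/2` in y, so adjacent axes are
#' exactly `pack_dist` apart. Consecutive repeats are related by a fixed rigid
#' repeat operator (translation along x plus `repeat_twist` about x). Loops are
#' straight CA paths. The build is deterministic for a fixed spec and errors if
#' the requested parameters produce steric clashes.
#'
#' @param spec A [repeat_spec()].
#' @return A [backbone()] with an extra element `helices`: a data.frame of the
#'   true helix boundaries (`index`, `chain`, `start`, `end`, `direction`), and
#'   `spec`, the generating spec.
#' @export
build_repeat_protein <- function(spec) {
  stopifnot(inherits(spec, "repeat_spec"))
  hl <- spec$helix_len; ll <- spec$loop_len
  nh <- 2L * spec$n_repeats
  height <- (hl - 1) * spec$helix_rise
  lat_y <- spec$pack_dist * sqrt(3) / 2
  # repeat operator: slide along x, optional twist about the x axis
  th <- spec$repeat_twist * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  rep_op <- rigid_transform(Rx, c(spec$pack_dist, 0, 0))
  # down-helix placement: 180 deg about y (runs -z), half a repeat over in x,
  # one lattice row over in y, residue 1 at the top
  flip <- rigid_transform(diag(c(-1, 1, -1)), c(spec$pack_dist / 2, lat_y, height))
  # helix j (1-based) starts at residue 1 + (j-1)*(hl+ll); a loop of ll
  # residues follows every helix but the last
  starts <- 1L + (seq_len(nh) - 1L) * (hl + ll)
  op <- rigid_transform() # cumulative repeat operator
  helices <- vector("list", nh)
  frames <- vector("list", nh) # repeat frame of each helix (for loop bulges)
  for (j in seq_len(nh)) {
    h <- ideal_helix(hl, spec$helix_rise, spec$helix_twist, phase = 25,
                     resno_start = starts[j])
    tr <- if (j %% 2L == 1L) op else compose_transform(op, flip)
    helices[[j]] <- bb_transform(h, tr)
    frames[[j]] <- op
    if (j %% 2L == 0L && j < nh) op <- compose_transform(rep_op, op)
  }
  parts <- lapply(helices, `[[`, "atoms")
  loops <- vector("list", nh - 1L)
  for (j in seq_len(nh - 1L)) {
    ca_from <- atom_coords(helices[[j]], "CA")[hl, ]
    ca_to <- atom_coords(helices[[j + 1L]], "CA")[1, ]
    # loops after up helices sit at the top of the bundle (bulge +z), loops
    # after down helices at the bottom (bulge -z); bulges follow the local
    # repeat frame so all repeats are exactly congruent
    bd <- as.numeric(frames[[j]]$rotation %*%
                       (if (j %% 2L == 1L) c(0, 0, 1) else c(0, 0, -1)))
    loops[[j]] <- .loop_atoms(ca_from, ca_to, ll, "A", starts[j] + hl,
                              bulge_dir = bd)
  }
  atoms <- do.call(rbind, c(parts, loops[!vapply(loops, is.null, logical(1))]))
  bb <- backbone(atoms)
  cl <- clash_count(bb)
  if (cl > 0) {
    cc <- .clash_pairs(bb)[1, ]
    stop("repeat spec produces ", cl, " steric clash(es); first: residues ",
         cc$res_i, " and ", cc$res_j, " at ", round(cc$dist, 2), " A")
  }
  bb$helices <- data.frame(index = seq_len(nh), chain = "A", start = starts,
                           end = starts + hl - 1L,
                           direction = rep(c("up", "down"), spec$n_repeats))
  bb$spec <- spec
  bb
}
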