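#' Hinge generation specification
#'
#' @param pivot_index Index (in helix order) of the pivot helix; must be
#'   neither the first nor the last helix.
#' @param shift_s Register shift in residues (nonzero for a nontrivial second
#'   state). Positive shifts slide the copy toward the C-terminal end of the
#'   pivot axis.
#' @param peptide_rule `"following_original"` (the helix after the pivot, in
#'   the original frame) or `"preceding_copy"` (the pivot helix of the rotated
#'   copy).
#' @return List of class `hinge_spec`.
#' @export
hinge_spec <- function(pivot_index, shift_s,
                       peptide_rule = c("following_original", "preceding_copy")) {
  peptide_rule <- match.arg(peptide_rule)
  stopifnot(pivot_index >= 1, abs(shift_s) >= 1)
  structure(list(pivot_index = as.integer(pivot_index),
                 shift_s = as.integer(shift_s), peptide_rule = peptide_rule),
            class = "hinge_spec")
}

#' Pivot-helix register-shift transform
#'
#' Superposes the pivot-helix CA window onto the same window shifted by
#' `shift_s` residues. On an ideal helix this is a screw motion about the
#' pivot axis with angle ~ `shift_s * twist` and translation ~
#' `shift_s * rise` along the axis.
#'
#' @param parent A [backbone()].
#' @param pivot A helix segment: list/row with `chain`, `start`, `end`.
#' @param shift_s Integer register shift; the window overlap
#'   (`length - |shift_s|`) must be at least 8 residues.
#' @return A [rigid_transform()] with attributes `rmsd` (superposition RMSD)
#'   and `irregular` (TRUE when RMSD > 0.7 A: pivot not regular enough).
#' @export
pivot_shift_transform <- function(parent, pivot, shift_s) {
  shift_s <- as.integer(shift_s)
  len <- pivot$end - pivot$start + 1
  if (len - abs(shift_s) < 8)
    stop("pivot overlap too short: need pivot length - |shift_s| >= 8")
  if (shift_s == 0) {
    tr <- rigid_transform()
    attr(tr, "rmsd") <- 0; attr(tr, "irregular") <- FALSE
    return(tr)
  }
  sel <- function(from, to) {
    i <- parent$residues$chain == pivot$chain &
      parent$residues$resno >= from & parent$residues$resno <= to
    atom_coords(parent, "CA")[i, , drop = FALSE]
  }
  # residues i with i+s also inside the pivot
  i0 <- max(pivot$start, pivot$start - shift_s)
  i1 <- min(pivot$end, pivot$end - shift_s)
  mob <- sel(i0, i1)                     # window at i
  tgt <- sel(i0 + shift_s, i1 + shift_s) # window at i + s
  fit <- superpose(mob, tgt)
  tr <- fit$transform
  attr(tr, "rmsd") <- fit$rmsd
  attr(tr, "irregular") <- fit$rmsd > 0.7
  if (fit$rmsd > 0.7)
    warning("pivot-shift superposition RMSD ", round(fit$rmsd, 2),
            " A > 0.7 A: pivot helix not regular enough")
  tr
}

#' Assemble the two hinge states and the effector peptide
#'
#' State X is the parent itself. State Y keeps helices 1..p (and their internal
#' loops) in the original frame as domain 1 and places helices p+1..n (and
#' their internal loops) under the pivot-shift transform as domain 2; the loop
#' between the domains is severed and its required span recorded. The peptide
#' is the helix following the pivot in the original frame
#' (`following_original`) or the transformed pivot helix (`preceding_copy`).
#'
#' @param parent A [backbone()] with at least 4 detectable helices.
#' @param spec A [hinge_spec()]; `1 < pivot_index < n_helices`.
#' @param helices Optional helix table (`chain`,`start`,`end`); detected from
#'   the parent when omitted.
#' @return Object of class `hinge_states`: `state_x`, `state_y`, `peptide`
#'   (chain B), `complex_y` (state Y plus peptide), `transform`, `spec`,
#'   `helices`, `domain` (per-helix domain assignment) and `report` (clash
#'   counts, gate energies, loop gap, screw angle/slide).
#' @export
assemble_states <- function(parent, spec, helices = NULL) {
  stopifnot(inherits(spec, "hinge_spec"))
  if (is.null(helices)) helices <- detect_helices(parent)
  n <- nrow(helices)
  if (n < 4) stop("parent must have at least 4 helices (found ", n, ")")
  p <- spec$pivot_index
  if (p <= 1 || p >= n)
    stop("pivot_index must be strictly between the first and last helix")
  tr <- pivot_shift_transform(parent, helices[p, ], spec$shift_s)
  # domain split by residue number: everything up to the end of helix p is
  # domain 1, everything from the start of helix p+1 is domain 2; the loop
  # between is severed
  d1_end <- helices$end[p]
  d2_start <- helices$start[p + 1]
  ch <- helices$chain[p]
  res <- parent$residues$resno[parent$residues$chain == ch]
  d1 <- bb_subset(parent, chain = ch, resno = res[res <= d1_end])
  d2 <- bb_transform(bb_subset(parent, chain = ch, resno = res[res >= d2_start]), tr)
  state_y <- bb_combine(d1, d2)
  peptide <- switch(spec$peptide_rule,
    following_original = bb_subset(parent, chain = ch,
                                   resno = helices$start[p + 1]:helices$end[p + 1]),
    preceding_copy = bb_transform(
      bb_subset(parent, chain = ch, resno = helices$start[p]:helices$end[p]), tr))
  peptide$atoms$chain <- "B"
  peptide <- backbone(peptide$atoms, validate = FALSE)
  complex_y <- bb_combine(state_y, peptide)
  states <- structure(list(state_x = parent, state_y = state_y,
                           peptide = peptide, complex_y = complex_y,
                           transform = tr, spec = spec, helices = helices,
                           d1_end = d1_end, d2_start = d2_start),
                      class = "hinge_states")
  # loop gap in state Y: last domain-1 CA to first domain-2 CA
  ca_y <- atom_coords(state_y, "CA")
  i_last <- max(which(state_y$residues$resno <= d1_end))
  i_first <- min(which(state_y$residues$resno >= d2_start))
  gap <- sqrt(sum((ca_y[i_first, ] - ca_y[i_last, ])^2))
  sd <- screw_decompose(tr)
  gate <- two_state_gate(states)
  states$report <- list(
    clash_x = clash_count(parent), clash_y = clash_count(state_y),
    clash_complex = clash_count(complex_y),
    energies = gate$energies, gate = gate[c("pass_x_lower",
                                            "pass_complex_lower", "pass")],
    loop_gap = gap, loop_residues_removed = sum(res > d1_end & res < d2_start),
    loop_feasible = loop_feasibility(gap, sum(res > d1_end & res < d2_start)),
    screw_angle = sd$angle_deg, screw_slide = sd$slide,
    pivot_rmsd = attr(tr, "rmsd"), pivot_irregular = attr(tr, "irregular"))
  states
}

#' @export
print.hinge_states <- function(x, ...) {
  cat("hinge_states: pivot helix", x$spec$pivot_index, "shift",
      x$spec$shift_s, "(", x$spec$peptide_rule, ")\n")
  cat("  screw:", sprintf("%.1f deg / %.2f A", x$report$screw_angle,
                          x$report$screw_slide),
      " loop gap:", sprintf("%.1f A", x$report$loop_gap), "\n")
  cat("  gate:", if (x$report$gate$pass) "PASS" else "fail",
      sprintf("(E_x %.0f, E_y %.0f, E_complex %.0f)",
              x$report$energies$e_x, x$report$energies$e_y_hinge,
              x$report$energies$e_complex), "\n")
  invisible(x)
}

# all clashing pairs via brute force (small n); used for error messages
.clash_pairs <- function(bb, cutoff = 3.2, bonded_exclusion = 2) {
  a <- bb$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  sep <- abs(outer(a$resno, a$resno, "-"))
  diffchain <- outer(a$chain, a$chain, "!=")
  hit <- which(upper.tri(d) & d < cutoff & (diffchain | sep > bonded_exclusion),
               arr.ind = TRUE)
  data.frame(res_i = a$resno[hit[, 1]], res_j = a$resno[hit[, 2]],
             dist = d[hit])
}

#' Count steric clashes
#'
#' Number of backbone/CB heavy-atom pairs closer than `cutoff` between
#' residues separated by more than `bonded_exclusion` positions in sequence
#' (or on different chains). Uses a spatial cell grid; identical to the
#' all-pairs answer.
#'
#' @param model A [backbone()].
#' @param cutoff Distance cutoff, A (default 3.2).
#' @param bonded_exclusion Sequence-separation exclusion (default 2).
#' @return Integer clash count.
#' @export
clash_count <- function(model, cutoff = 3.2, bonded_exclusion = 2) {
  a <- model$atoms
  n <- nrow(a)
  if (n < 2) return(0L)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  cell <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cutoff)
  keyof <- function(cx, cy, cz) paste(cx, cy, cz)
  key <- keyof(cell[, 1], cell[, 2], cell[, 3])
  buckets <- split(seq_len(n), key)
  count <- 0L
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (b in names(buckets)) {
    i <- buckets[[b]]
    c0 <- cell[i[1], ]
    nb_keys <- keyof(c0[1] + offsets[, 1], c0[2] + offsets[, 2],
                     c0[3] + offsets[, 3])
    j <- unlist(buckets[intersect(nb_keys, names(buckets))], use.names = FALSE)
    for (ii in i) {
      jj <- j[j > ii]
      if (!length(jj)) next
      d2 <- rowSums((xyz[jj, , drop = FALSE] -
                       matrix(xyz[ii, ], length(jj), 3, byrow = TRUE))^2)
      ok <- d2 < cutoff^2 &
        (a$chain[jj] != a$chain[ii] | abs(a$resno[jj] - a$resno[ii]) > bonded_exclusion)
      count <- count + sum(ok)
    }
  }
  as.integer(count)
}

#' Surrogate two-state contact energy
#'
#' `E = -(number of inter-segment CB-CB pairs < r_contact) + 25 * clash_count`.
#' Lower is better. This is a contact count standing in for a physical
#' potential: it reproduces the two-state selection logic (which state is
#' favoured), not physical energy values.
#'
#' @param model A [backbone()] with CBs built.
#' @param partition Integer/character vector assigning each residue of `model`
#'   (in residue order) to exactly one rigid segment.
#' @param r_contact CB-CB contact cutoff, A (default 8).
#' @return Numeric energy (0 for an empty model).
#' @export
contact_energy <- function(model, partition, r_contact = 8) {
  if (n_residues(model) == 0) return(0)
  stopifnot(length(partition) == n_residues(model))
  cb <- atom_coords(model, "CB")
  ok <- !is.na(cb[, 1])
  cb <- cb[ok, , drop = FALSE]
  part <- partition[ok]
  ncontact <- 0L
  if (nrow(cb) > 1) {
    d <- as.matrix(stats::dist(cb))
    inter <- outer(part, part, "!=")
    ncontact <- sum(d < r_contact & inter & upper.tri(d))
  }
  -ncontact + 25 * clash_count(model)
}

# residue -> owning helix segment; loop residues join the preceding helix
# (N-terminal tails join the first helix)
.segment_partition <- function(bb, helices) {
  res <- bb$residues$resno
  seg <- rep(NA_integer_, length(res))
  for (i in seq_len(nrow(helices)))
    seg[res >= helices$start[i] & res <= helices$end[i]] <- i
  for (k in seq_along(seg)) {
    if (is.na(seg[k])) seg[k] <- if (k > 1) seg[k - 1] else 1L
  }
  seg
}

#' Two-state energy gate
#'
#' A design passes when (i) state X has lower contact energy than the state Y
#' hinge alone (the unbound hinge prefers X) and (ii) the state Y complex has
#' lower energy than state X plus the spatially separated peptide (binding
#' pays for the switch). Energies use [contact_energy()] with a per-helix
#' partition (peptide is its own segment); an isolated peptide has energy 0 by
#' construction.
#'
#' @param states A [assemble_states()] result.
#' @return List: `pass_x_lower`, `pass_complex_lower`, `pass`, `energies`
#'   (`e_x`, `e_y_hinge`, `e_complex`, `e_peptide`).
#' @export
two_state_gate <- function(states) {
  hx <- build_cb(states$state_x)
  hy <- build_cb(states$state_y)
  cpx <- build_cb(states$complex_y)
  pep <- build_cb(states$peptide)
  part_x <- .segment_partition(hx, states$helices)
  part_y <- .segment_partition(hy, states$helices)
  part_c <- c(part_y, rep(0L, n_residues(pep))) # peptide = its own segment
  e_x <- contact_energy(hx, part_x)
  e_y <- contact_energy(hy, part_y)
  e_c <- contact_energy(cpx, part_c)
  e_p <- contact_energy(pep, rep(1L, n_residues(pep)))
  list(pass_x_lower = e_x < e_y,
       pass_complex_lower = e_c < e_x + e_p,
       pass = e_x < e_y && e_c < e_x + e_p,
       energies = list(e_x = e_x, e_y_hinge = e_y, e_complex = e_c,
                       e_peptide = e_p))
}

# CB coordinates indexed by residue number, plus a surface mask: a residue is
# surface-exposed when its CB has <= 14 CB neighbours within 10 A
.cb_frame <- function(bb) {
  b <- build_cb(bb)
  cb <- atom_coords(b, "CB")
  nb <- rowSums(as.matrix(stats::dist(cb)) < 10) - 1
  list(resno = b$residues$resno, cb = cb, surface = nb <= 14)
}

#' Candidate spectroscopic label-site pairs
#'
#' Pairs one surface residue of domain 1 with one of domain 2 and reports the
#' CB-CB distance in each state and the change `delta = d_y - d_x`. A residue
#' counts as surface when its CB has at most 14 CB neighbours within 10 A in
#' both states (burial proxy). Pairs are ranked by `|delta|` descending,
#' filtered by sign (`increase`: larger in state Y, `decrease`: smaller), ties
#' broken by smaller `res_i` then `res_j`.
#'
#' @param states A [assemble_states()] result.
#' @param mode `"increase"` or `"decrease"`.
#' @param top_k Maximum number of pairs returned (default 20).
#' @return data.frame `res_i`, `res_j`, `d_x`, `d_y`, `delta` (may be empty).
#' @export
site_pairs <- function(states, mode = c("increase", "decrease"), top_k = 20) {
  mode <- match.arg(mode)
  pairs <- .domain_pair_table(states)
  pairs <- pairs[if (mode == "increase") pairs$delta > 0 else pairs$delta < 0, ]
  pairs <- pairs[order(-abs(pairs$delta), pairs$res_i, pairs$res_j), ]
  utils::head(pairs, top_k)
}

.domain_pair_table <- function(states, surface_only = TRUE) {
  fx <- .cb_frame(bb_subset(states$state_x, chain = states$helices$chain[1]))
  fy <- .cb_frame(states$state_y)
  # align by residue number (state Y lacks the severed loop residues)
  common <- intersect(fx$resno, fy$resno)
  ix <- match(common, fx$resno); iy <- match(common, fy$resno)
  surf <- fx$surface[ix] & fy$surface[iy]
  keep <- if (surface_only) surf else rep(TRUE, length(common))
  d1 <- common <= states$d1_end
  i_set <- which(keep & d1); j_set <- which(keep & !d1)
  if (!length(i_set) || !length(j_set))
    return(data.frame(res_i = integer(0), res_j = integer(0),
                      d_x = numeric(0), d_y = numeric(0), delta = numeric(0)))
  g <- expand.grid(i = i_set, j = j_set)
  dx <- sqrt(rowSums((fx$cb[ix[g$i], , drop = FALSE] -
                        fx$cb[ix[g$j], , drop = FALSE])^2))
  dy <- sqrt(rowSums((fy$cb[iy[g$i], , drop = FALSE] -
                        fy$cb[iy[g$j], , drop = FALSE])^2))
  data.frame(res_i = common[g$i], res_j = common[g$j],
             d_x = dx, d_y = dy, delta = dy - dx)
}

#' Candidate disulfide staple sites
#'
#' Residue pairs whose CB-CB distance is within disulfide bonding range in the
#' state to lock and far apart in the other state, so an oxidised bond is
#' geometrically possible in one conformation only. Ranked by centrality of
#' the in-range distance, then by residue indices.
#'
#' @param states A [assemble_states()] result.
#' @param lock_state `"X"` or `"Y"`: the state in which the bond forms.
#' @param d_bond Length-2 bonding window, A (default `c(3.5, 5.5)`).
#' @param d_excl Minimum CB-CB distance in the other state, A (default 10).
#' @return data.frame `res_i`, `res_j`, `d_x`, `d_y`, `delta` (may be empty).
#' @export
staple_candidates <- function(states, lock_state = c("X", "Y"),
                              d_bond = c(3.5, 5.5), d_excl = 10) {
  lock_state <- match.arg(lock_state)
  pairs <- .domain_pair_table(states, surface_only = FALSE)
  din <- if (lock_state == "X") pairs$d_x else pairs$d_y
  dout <- if (lock_state == "X") pairs$d_y else pairs$d_x
  sel <- din >= d_bond[1] & din <= d_bond[2] & dout > d_excl
  pairs <- pairs[sel, ]
  din <- din[sel]
  pairs[order(abs(din - mean(d_bond)), pairs$res_i, pairs$res_j), ]
}

#' Geometric loop-closure feasibility
#'
#' A gap of `gap` Angstrom can be bridged by `n_loop_residues` residues when
#' `gap <= 3.8 * (n_loop_residues + 1)` (each added residue contributes at
#' most one CA-CA virtual bond of 3.8 A).
#'
#' @param gap Gap distance, A (>= 0).
#' @param n_loop_residues Number of loop residues (>= 0).
#' @return Logical.
#' @export
loop_feasibility <- function(gap, n_loop_residues) {
  if (gap < 0 || n_loop_residues < 0)
    stop("gap and n_loop_residues must be non-negative")
  gap <= 3.8 * (n_loop_residues + 1)
}
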