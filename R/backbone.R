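#' Backbone structure container
#'
#' Holds per-residue backbone coordinates (N, CA, C, optional O and CB) with
#' chain annotation. This is the substrate of every geometric operation in the
#' package: helix detection, pivot-shift state generation, contact energies and
#' label-site selection.
#'
#' @param atoms data.frame with columns `chain` (single-character id), `resno`
#'   (1-based integer, strictly increasing within a chain), `elety` (one of
#'   N, CA, C, O, CB), `x`, `y`, `z` (Angstrom).
#' @param validate check invariants (every residue has N, CA, C; consecutive
#'   CA-CA distances are not impossibly short). Chain breaks (CA-CA > 4.2 A)
#'   are recorded as segment boundaries, not errors.
#' @return Object of class `backbone`: a list with `atoms` (the atom table) and
#'   `residues` (one row per residue: chain, resno, segment id).
#' @export
backbone <- function(atoms, validate = TRUE) {
  stopifnot(is.data.frame(atoms),
            all(c("chain", "resno", "elety", "x", "y", "z") %in% names(atoms)))
  atoms <- atoms[, c("chain", "resno", "elety", "x", "y", "z")]
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  bad <- setdiff(unique(atoms$elety), c("N", "CA", "C", "O", "CB"))
  if (length(bad))
    stop("unsupported atom names: ", paste(bad, collapse = ", "))
  # canonical ordering: file chain order, then resno, then atom order
  chain_order <- unique(atoms$chain)
  atoms <- atoms[order(match(atoms$chain, chain_order), atoms$resno,
                       match(atoms$elety, c("N", "CA", "C", "O", "CB"))), ]
  rownames(atoms) <- NULL
  res <- unique(atoms[, c("chain", "resno")])
  rownames(res) <- NULL
  if (validate) {
    key <- paste(atoms$chain, atoms$resno)
    for (a in c("N", "CA", "C")) {
      have <- unique(key[atoms$elety == a])
      miss <- setdiff(paste(res$chain, res$resno), have)
      if (length(miss))
        stop("missing backbone atom ", a, " for residue(s): ",
             paste(utils::head(miss, 5), collapse = "; "))
    }
    for (ch in unique(res$chain)) {
      rn <- res$resno[res$chain == ch]
      if (any(diff(rn) <= 0))
        stop("res_index not strictly increasing in chain ", ch)
    }
  }
  obj <- structure(list(atoms = atoms, residues = res), class = "backbone")
  obj$residues$segment <- .segment_ids(obj)
  if (validate) {
    ca <- atom_coords(obj, "CA")
    for (ch in unique(res$chain)) {
      i <- which(res$chain == ch)
      if (length(i) < 2) next
      adj <- which(diff(res$resno[i]) == 1)
      d <- sqrt(rowSums((ca[i[adj + 1], , drop = FALSE] -
                           ca[i[adj], , drop = FALSE])^2))
      if (any(d < 2.8))
        stop("impossible CA-CA virtual bond (< 2.8 A) in chain ", ch,
             " at residue ", res$resno[i[adj[which(d < 2.8)[1]]]])
    }
  }
  obj
}

# segment ids: split at chain boundaries, resno gaps, and CA-CA breaks > 4.2 A
.segment_ids <- function(bb) {
  res <- bb$residues
  ca <- atom_coords(bb, "CA")
  n <- nrow(res)
  if (n == 0) return(integer(0))
  brk <- logical(n)
  brk[1] <- TRUE
  if (n > 1) {
    same_chain <- res$chain[-1] == res$chain[-n]
    consec <- res$resno[-1] - res$resno[-n] == 1
    d <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE])^2))
    brk[-1] <- !(same_chain & consec & d <= 4.2)
  }
  cumsum(brk)
}

#' @export
print.backbone <- function(x, ...) {
  cat("backbone:", nrow(x$residues), "residues,",
      length(unique(x$residues$chain)), "chain(s),",
      max(x$residues$segment, 0), "segment(s),",
      nrow(x$atoms), "atoms\n")
  invisible(x)
}

#' Number of residues in a backbone
#' @param bb A [backbone()].
#' @return Integer count.
#' @export
n_residues <- function(bb) nrow(bb$residues)

#' Extract coordinates of one atom type, in residue order
#'
#' @param bb A [backbone()].
#' @param elety Atom name (default "CA").
#' @return n x 3 matrix with one row per residue carrying that atom; rows for
#'   residues lacking the atom are NA.
#' @export
atom_coords <- function(bb, elety = "CA") {
  a <- bb$atoms[bb$atoms$elety == elety, ]
  key <- paste(bb$residues$chain, bb$residues$resno)
  m <- matrix(NA_real_, nrow(bb$residues), 3)
  idx <- match(paste(a$chain, a$resno), key)
  m[idx, ] <- as.matrix(a[, c("x", "y", "z")])
  m
}

#' Subset a backbone by chain and/or residue numbers
#'
#' @param bb A [backbone()].
#' @param chain Optional chain id(s) to keep.
#' @param resno Optional residue numbers to keep (applied after chain filter).
#' @return A `backbone` containing the selected residues.
#' @export
bb_subset <- function(bb, chain = NULL, resno = NULL) {
  a <- bb$atoms
  if (!is.null(chain)) a <- a[a$chain %in% chain, ]
  if (!is.null(resno)) a <- a[a$resno %in% resno, ]
  backbone(a, validate = FALSE)
}

#' Combine backbones into one structure
#'
#' @param ... `backbone` objects.
#' @param chains Optional character vector re-assigning one chain id per input.
#' @return A combined `backbone`.
#' @export
bb_combine <- function(..., chains = NULL) {
  parts <- list(...)
  if (!is.null(chains)) {
    stopifnot(length(chains) == length(parts))
    parts <- Map(function(p, ch) { p$atoms$chain <- ch; p }, parts, chains)
  }
  backbone(do.call(rbind, lapply(parts, `[[`, "atoms")), validate = FALSE)
}

#' Apply a rigid transform to a backbone
#'
#' @param bb A [backbone()].
#' @param transform A [rigid_transform()].
#' @return The transformed `backbone`.
#' @export
bb_transform <- function(bb, transform) {
  xyz <- apply_transform(transform, as.matrix(bb$atoms[, c("x", "y", "z")]))
  bb$atoms[, c("x", "y", "z")] <- xyz
  bb
}

#' Read a backbone from a PDB file
#'
#' Keeps ATOM records for N, CA, C, O and CB only; waters and hetero records
#' are skipped. Alternate locations are resolved to the highest occupancy, ties
#' broken by altloc identifier order. Chain breaks (CA-CA > 4.2 A) become
#' segment boundaries, not errors; a residue missing N, CA or C is a hard
#' error naming the chain and residue.
#'
#' @param path PDB file path.
#' @return A [backbone()].
#' @export
read_backbone <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  a <- a[a$type == "ATOM" & a$elety %in% c("N", "CA", "C", "O", "CB"), ]
  if (nrow(a) == 0) stop("no backbone ATOM records found in ", path)
  a$chain[is.na(a$chain)] <- "A"
  a$o[is.na(a$o)] <- 1
  a$alt[is.na(a$alt)] <- ""
  # altloc policy: highest occupancy, ties by altloc identifier order
  key <- paste(a$chain, a$resno, a$elety)
  a <- a[order(key, -a$o, a$alt), ]
  a <- a[!duplicated(paste(a$chain, a$resno, a$elety)), ]
  backbone(data.frame(chain = a$chain, resno = a$resno, elety = a$elety,
                      x = a$x, y = a$y, z = a$z))
}

#' Write a backbone to a PDB file
#'
#' ATOM records only; occupancy 1.00, B-factor 0.00; residues written as ALA
#' (GLY when no CB is present).
#'
#' @param bb A [backbone()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_backbone <- function(bb, path) {
  a <- bb$atoms
  key <- paste(a$chain, a$resno)
  has_cb <- key %in% key[a$elety == "CB"]
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, chain = a$chain, elety = a$elety,
                   resid = ifelse(has_cb, "ALA", "GLY"),
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(path)
}

# ideal CB placement frame: tilt out of the N-CA-C bisector plane chosen to
# give the standard L-amino-acid geometry (N-CA-CB ~ 110.2 deg)
.CB_LENGTH <- 1.521
.CB_ALPHA <- 52.25 * pi / 180

#' Add ideal CB atoms
#'
#' Places a CB at 1.521 A from each CA using standard tetrahedral geometry
#' derived from the N, CA, C positions (L-amino-acid chirality). Residues that
#' already carry a CB are left untouched. Ideal CBs make every downstream
#' contact, staple and label-site distance sequence-independent.
#'
#' @param bb A [backbone()].
#' @return A `backbone` in which every residue has a CB.
#' @export
build_cb <- function(bb) {
  key <- paste(bb$residues$chain, bb$residues$resno)
  have <- key %in% paste(bb$atoms$chain, bb$atoms$resno)[bb$atoms$elety == "CB"]
  if (all(have)) return(bb)
  N <- atom_coords(bb, "N"); CA <- atom_coords(bb, "CA"); C <- atom_coords(bb, "C")
  idx <- which(!have)
  u1 <- N[idx, , drop = FALSE] - CA[idx, , drop = FALSE]
  u2 <- C[idx, , drop = FALSE] - CA[idx, , drop = FALSE]
  u1 <- u1 / sqrt(rowSums(u1^2)); u2 <- u2 / sqrt(rowSums(u2^2))
  e1 <- u1 + u2; e1 <- e1 / sqrt(rowSums(e1^2))
  e3 <- cbind(u1[, 2] * u2[, 3] - u1[, 3] * u2[, 2],
              u1[, 3] * u2[, 1] - u1[, 1] * u2[, 3],
              u1[, 1] * u2[, 2] - u1[, 2] * u2[, 1])
  e3 <- e3 / sqrt(rowSums(e3^2))
  dirn <- -e1 * cos(.CB_ALPHA) + e3 * sin(.CB_ALPHA)
  cb <- CA[idx, , drop = FALSE] + .CB_LENGTH * dirn
  new <- data.frame(chain = bb$residues$chain[idx],
                    resno = bb$residues$resno[idx], elety = "CB",
                    x = cb[, 1], y = cb[, 2], z = cb[, 3])
  backbone(rbind(bb$atoms, new), validate = FALSE)
}

#' Detect helical segments from CA geometry
#'
#' A residue window is called helical when the CA(i) to CA(i+3) distance lies
#' in \[4.5, 5.7\] A and the CA(i..i+3) virtual torsion lies in \[40, 60\]
#' degrees. Maximal runs of helical windows are reported; runs shorter than
#' `min_len` residues are dropped. Chains and chain-break segments are treated
#' independently, so segments never overlap.
#'
#' @param bb A [backbone()].
#' @param min_len Minimum helix length in residues (default 6).
#' @return data.frame with one row per helix: `chain`, `start`, `end`
#'   (inclusive residue numbers). May have zero rows.
#' @export
detect_helices <- function(bb, min_len = 6) {
  ca <- atom_coords(bb, "CA")
  res <- bb$residues
  out <- list()
  for (seg in unique(res$segment)) {
    i <- which(res$segment == seg)
    if (length(i) < max(min_len, 4)) next
    p <- ca[i, , drop = FALSE]
    n <- nrow(p)
    d13 <- sqrt(rowSums((p[4:n, , drop = FALSE] - p[1:(n - 3), , drop = FALSE])^2))
    tor <- vapply(1:(n - 3), function(k) .dihedral(p[k, ], p[k + 1, ], p[k + 2, ], p[k + 3, ]),
                  numeric(1))
    ok <- d13 >= 4.5 & d13 <= 5.7 & tor >= 40 & tor <= 60
    r <- rle(ok)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      first <- starts[j]; last <- ends[j] + 3 # window i covers residues i..i+3
      if (last - first + 1 < min_len) next
      out[[length(out) + 1]] <- data.frame(chain = res$chain[i[first]],
                                           start = res$resno[i[first]],
                                           end = res$resno[i[last]])
    }
  }
  if (!length(out))
    return(data.frame(chain = character(0), start = integer(0), end = integer(0)))
  do.call(rbind, out)
}

.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma::cross(b1, b2); n2 <- pracma::cross(b2, b3)
  m1 <- pracma::cross(n1, b2 / sqrt(sum(b2^2)))
  -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi # IUPAC sign
}

#' Fit a helix axis, rise and twist to a residue range
#'
#' The axis direction is the total-least-squares normal to the CA second
#' differences (which point radially inward on a regular helix); the axis point
#' and radius come from an algebraic circle fit of the CAs projected onto the
#' plane perpendicular to the axis. Rise is the mean per-residue displacement
#' along the axis and twist the mean per-residue rotation about it. The axis is
#' oriented along increasing residue number, so reversing the residue order
#' negates `axis_dir` and leaves rise/twist unchanged.
#'
#' @param bb A [backbone()].
#' @param chain Chain id of the segment.
#' @param start,end Inclusive residue-number range (length >= 6).
#' @return List of class `helix_segment`: `chain`, `start`, `end`,
#'   `axis_point`, `axis_dir` (unit), `rise` (A/res), `twist` (deg/res),
#'   `radius`, `residual` (RMS cylinder deviation, A) and logical `flagged`
#'   (TRUE when the residual exceeds 1.0 A; the axis is still returned).
#' @export
fit_helix_axis <- function(bb, chain, start, end) {
  sel <- bb$residues$chain == chain & bb$residues$resno >= start &
    bb$residues$resno <= end
  p <- atom_coords(bb, "CA")[sel, , drop = FALSE]
  n <- nrow(p)
  if (n < 6) stop("helix segment must span at least 6 residues")
  W <- p[1:(n - 2), , drop = FALSE] - 2 * p[2:(n - 1), , drop = FALSE] +
    p[3:n, , drop = FALSE]
  d <- svd(W)$v[, 3]
  proj <- as.numeric(p %*% d)
  if (mean(diff(proj)) < 0) { d <- -d; proj <- -proj }
  # orthonormal in-plane frame
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- pracma::cross(d, ref); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- pracma::cross(d, e1)
  uv <- cbind(as.numeric(p %*% e1), as.numeric(p %*% e2))
  # Kasa algebraic circle fit
  sol <- qr.solve(cbind(2 * uv, 1), rowSums(uv^2))
  ctr <- sol[1:2]
  radius <- sqrt(max(sol[3] + sum(ctr^2), 0))
  rel <- sweep(uv, 2, ctr)
  residual <- sqrt(mean((sqrt(rowSums(rel^2)) - radius)^2))
  ang <- atan2(rel[, 2], rel[, 1])
  dtw <- diff(ang); dtw <- (dtw + pi) %% (2 * pi) - pi
  # signed about +d, then reported as the magnitude (alpha-helices ~ +100 deg)
  twist <- abs(mean(dtw)) * 180 / pi
  axis_point <- ctr[1] * e1 + ctr[2] * e2
  structure(list(chain = chain, start = start, end = end,
                 axis_point = as.numeric(axis_point), axis_dir = as.numeric(d),
                 rise = mean(diff(proj)), twist = twist, radius = radius,
                 residual = residual, flagged = residual > 1.0),
            class = "helix_segment")
}

#' Detect helices and fit all axes
#'
#' Convenience wrapper: [detect_helices()] followed by [fit_helix_axis()] on
#' each segment.
#'
#' @inheritParams detect_helices
#' @return data.frame with columns `chain`, `start`, `end`, `rise`, `twist`,
#'   `residual`, `flagged`, plus list-columns `axis_point` and `axis_dir`.
#' @export
helix_table <- function(bb, min_len = 6) {
  h <- detect_helices(bb, min_len = min_len)
  if (nrow(h) == 0) {
    h$rise <- h$twist <- h$residual <- numeric(0)
    h$flagged <- logical(0)
    return(h)
  }
  fits <- lapply(seq_len(nrow(h)), function(i)
    fit_helix_axis(bb, h$chain[i], h$start[i], h$end[i]))
  h$rise <- vapply(fits, `[[`, numeric(1), "rise")
  h$twist <- vapply(fits, `[[`, numeric(1), "twist")
  h$residual <- vapply(fits, `[[`, numeric(1), "residual")
  h$flagged <- vapply(fits, `[[`, logical(1), "flagged")
  h$axis_point <- lapply(fits, `[[`, "axis_point")
  h$axis_dir <- lapply(fits, `[[`, "axis_dir")
  h
}

#' Write a helix table as CSV
#'
#' Emits `chain,start,end,rise,twist,residual` rows.
#'
#' @param helices Output of [helix_table()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_helix_csv <- function(helices, path) {
  utils::write.csv(helices[, c("chain", "start", "end", "rise", "twist",
                               "residual")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
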