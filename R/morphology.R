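#' @useDynLib golgicell, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import tibble
#' @importFrom rlang .data abort warn
#' @importFrom stats setNames
NULL

SECTION_LABELS <- c("soma", "axon", "AIS", "basal_dendrite", "apical_dendrite")

# SWC type codes: 1 soma, 2 axon, 3 basal dendrite, 4 apical dendrite
swc_type_to_label <- function(type) {
  lab <- rep(NA_character_, length(type))
  lab[type == 1] <- "soma"
  lab[type == 2] <- "axon"
  lab[type == 3] <- "basal_dendrite"
  lab[type == 4] <- "apical_dendrite"
  lab[is.na(lab)] <- "basal_dendrite" # unknown codes treated as dendrite
  lab
}

label_to_swc_type <- function(label) {
  unname(c(soma = 1L, axon = 2L, AIS = 2L,
           basal_dendrite = 3L, apical_dendrite = 4L)[label])
}

#' Read a neuron morphology from an SWC file
#'
#' Parses the whitespace-delimited 7-column SWC format used by
#' NeuroMorpho.org (`id type x y z radius parent`, `#` comments) and splits
#' the point tree into unbranched sections of uniform type. Type codes map to
#' initial section labels: 1 soma, 2 axon, 3 basal dendrite, 4 apical
#' dendrite. Use [classify_sections()] afterwards to resolve the
#' apical/basal split against a Purkinje-cell-layer boundary and to mark the
#' axon initial segment.
#'
#' @param path Path to an SWC file.
#' @return A `goc_morphology` object: a list with a `points` tibble, a
#'   `sections` tibble (one row per unbranched section, with a `point_ids`
#'   list-column whose first id is the attachment point on the parent
#'   section), and `provenance`.
#' @export
#' @examples
#' swc <- tempfile(fileext = ".swc")
#' writeLines(c("# soma only",
#'   "1 1 0 0 0 8 -1", "2 1 0 8 0 8 1", "3 1 0 16 0 8 2"), swc)
#' m <- read_swc(swc)
#' section_table(m)
read_swc <- function(path) {
  if (!file.exists(path)) abort(paste0("SWC file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0) abort("SWC file contains no data records")
  fields <- strsplit(trimws(lines[rows]), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 7)) {
    abort(sprintf("SWC parse error at line %d: expected 7 columns, found %d",
                  rows[which(nf != 7)[1]], nf[nf != 7][1]))
  }
  mat <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  if (anyNA(mat)) abort("SWC parse error: non-numeric field")
  pts <- tibble(
    id = as.integer(mat[, 1]), type = as.integer(mat[, 2]),
    x = mat[, 3], y = mat[, 4], z = mat[, 5],
    radius = mat[, 6], parent = as.integer(mat[, 7])
  )
  bad_r <- which(pts$radius <= 0)
  if (length(bad_r) > 0) {
    abort(sprintf("SWC parse error at line %d: radius must be > 0",
                  rows[bad_r[1]]))
  }
  if (anyDuplicated(pts$id)) abort("SWC parse error: duplicate point ids")
  known <- c(-1L, pts$id)
  if (!all(pts$parent %in% known)) {
    orphan <- pts$id[!(pts$parent %in% known)][1]
    abort(sprintf("SWC parse error: point %d references unknown parent", orphan))
  }
  new_morphology(pts, provenance = list(source = "swc", path = path))
}

# Build section tibble from a point table; sections are maximal unbranched
# runs of same-type points.
new_morphology <- function(points, provenance) {
  pts <- points[order(points$id), ]
  idx <- setNames(seq_len(nrow(pts)), pts$id)
  parent_idx <- ifelse(pts$parent < 0, NA_integer_, idx[as.character(pts$parent)])
  if (sum(is.na(parent_idx)) != 1) {
    abort("morphology must have exactly one root point")
  }
  nchild <- tabulate(parent_idx[!is.na(parent_idx)], nbins = nrow(pts))
  # a point starts a new section if: it is the root, its type differs from its
  # parent's, or its parent is a branch point (>1 children) or the parent is
  # a soma point while it is not
  starts <- vapply(seq_len(nrow(pts)), function(i) {
    p <- parent_idx[i]
    if (is.na(p)) return(TRUE)
    if (pts$type[i] != pts$type[p]) return(TRUE)
    if (pts$type[i] == 1) return(FALSE) # soma points form one section
    if (nchild[p] > 1) return(TRUE)
    FALSE
  }, logical(1))
  # walk each run from its start
  sec_of_point <- integer(nrow(pts))
  sec_rows <- list()
  start_ids <- which(starts)
  # order starts so parents come first (point order is topological since
  # parent id < own id)
  for (s in start_ids) {
    run <- s
    cur <- s
    repeat {
      kids <- which(parent_idx == cur & !starts)
      if (length(kids) != 1) break
      cur <- kids
      run <- c(run, cur)
    }
    sec_rows[[length(sec_rows) + 1]] <- run
    sec_of_point[run] <- length(sec_rows)
  }
  secs <- tibble(
    section_id = seq_along(sec_rows),
    label = vapply(sec_rows, function(r) swc_type_to_label(pts$type[r[1]]),
                   character(1)),
    parent_section = vapply(sec_rows, function(r) {
      p <- parent_idx[r[1]]
      if (is.na(p)) NA_integer_ else sec_of_point[p]
    }, integer(1)),
    point_ids = lapply(sec_rows, function(r) {
      p <- parent_idx[r[1]]
      ids <- pts$id[r]
      # prepend attachment point for geometry, except at the root
      if (!is.na(p) && swc_type_to_label(pts$type[r[1]]) != "soma") {
        ids <- c(pts$id[p], ids)
      }
      ids
    })
  )
  root_lab <- secs$label[is.na(secs$parent_section)]
  if (!identical(root_lab, "soma")) abort("morphology root must be a soma point")
  if (sum(secs$label == "soma") != 1) abort("morphology must have exactly one soma section")
  structure(list(points = pts, sections = secs, compartments = NULL,
                 provenance = provenance),
            class = "goc_morphology")
}

#' @export
print.goc_morphology <- function(x, ...) {
  tab <- table(factor(x$sections$label, levels = SECTION_LABELS))
  cat("<goc_morphology> ", nrow(x$points), " points, ",
      nrow(x$sections), " sections\n", sep = "")
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n", sep = "")
  cat("  total cable length: ", round(total_cable_length(x), 1), " um\n", sep = "")
  if (!is.null(x$compartments)) {
    cat("  discretized: ", nrow(x$compartments), " compartments\n", sep = "")
  }
  invisible(x)
}

section_points <- function(m, sec_row) {
  ids <- m$sections$point_ids[[sec_row]]
  p <- m$points[match(ids, m$points$id), ]
  # the soma attachment point contributes position only: a branch leaving the
  # soma keeps its own calibre rather than tapering from the soma radius
  if (nrow(p) >= 2 && p$type[1] == 1L && p$type[2] != 1L) {
    p$radius[1] <- p$radius[2]
  }
  p
}

section_length <- function(m, sec_row) {
  p <- section_points(m, sec_row)
  if (nrow(p) < 2) return(0)
  sum(sqrt(diff(p$x)^2 + diff(p$y)^2 + diff(p$z)^2))
}

# lateral area of the section polyline under the cylindrical-segment
# convention: each polyline segment contributes pi * mean(diameter) * length
section_area_um2 <- function(m, sec_row) {
  p <- section_points(m, sec_row)
  if (nrow(p) < 2) return(pi * (2 * p$radius[1])^2) # spherical single-point soma
  seg <- sqrt(diff(p$x)^2 + diff(p$y)^2 + diff(p$z)^2)
  sum(pi * (p$radius[-1] + p$radius[-nrow(p)]) * seg)
}

#' Total cable length of a morphology
#'
#' Sum of polyline path lengths over all sections, in micrometers.
#'
#' @param m A `goc_morphology`.
#' @param labels Optional subset of section labels to include.
#' @return Length in um.
#' @export
total_cable_length <- function(m, labels = NULL) {
  rows <- seq_len(nrow(m$sections))
  if (!is.null(labels)) rows <- rows[m$sections$label %in% labels]
  sum(vapply(rows, function(i) section_length(m, i), numeric(1)))
}

#' Summarize the sections of a morphology
#'
#' @param m A `goc_morphology`.
#' @return A tibble with one row per section: id, label, parent, number of
#'   points, path length (um) and membrane area (um^2).
#' @export
section_table <- function(m) {
  tibble(
    section_id = m$sections$section_id,
    label = m$sections$label,
    parent_section = m$sections$parent_section,
    n_points = lengths(m$sections$point_ids),
    length_um = vapply(seq_len(nrow(m$sections)),
                       function(i) section_length(m, i), numeric(1)),
    area_um2 = vapply(seq_len(nrow(m$sections)),
                      function(i) section_area_um2(m, i), numeric(1))
  )
}

#' Validate morphology invariants
#'
#' Checks that the object is a single connected tree rooted in exactly one
#' soma, that radii are positive, labels are from the allowed set, and that
#' any AIS is a contiguous proximal sub-path of the axon.
#'
#' @param m A `goc_morphology`.
#' @return Invisibly `TRUE`; aborts with a message describing the first
#'   violated invariant.
#' @export
validate_morphology <- function(m) {
  stopifnot(inherits(m, "goc_morphology"))
  if (any(m$points$radius <= 0)) abort("invariant violated: non-positive radius")
  if (!all(m$sections$label %in% SECTION_LABELS)) {
    abort("invariant violated: unknown section label")
  }
  if (sum(m$sections$label == "soma") != 1) {
    abort("invariant violated: must have exactly one soma section")
  }
  roots <- sum(is.na(m$sections$parent_section))
  if (roots != 1) abort("invariant violated: section tree must have one root")
  # connectivity / acyclicity: every section reaches the root
  for (i in seq_len(nrow(m$sections))) {
    seen <- integer(0)
    cur <- i
    while (!is.na(cur)) {
      if (cur %in% seen) abort("invariant violated: cycle in section tree")
      seen <- c(seen, cur)
      cur <- m$sections$parent_section[cur]
    }
  }
  nonsoma <- m$sections$label != "soma"
  if (any(lengths(m$sections$point_ids)[nonsoma] < 2)) {
    abort("invariant violated: non-soma section with fewer than 2 points")
  }
  # AIS contiguity: every AIS section's parent is soma, an AIS section, or the
  # dendrite the axon stems from; and no axon section may be parent of an AIS
  ais <- which(m$sections$label == "AIS")
  for (i in ais) {
    p <- m$sections$parent_section[i]
    if (!is.na(p) && m$sections$label[p] == "axon") {
      abort("invariant violated: AIS must be proximal to the axon")
    }
  }
  invisible(TRUE)
}

#' Write a morphology to an SWC file
#'
#' Inverse of [read_swc()]; AIS sections are written with the axon type code
#' (2), so `read_swc() |> classify_sections()` recovers the labels.
#'
#' @param m A `goc_morphology`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(m, path) {
  pts <- m$points
  # rewrite type codes from current section labels
  for (i in seq_len(nrow(m$sections))) {
    ids <- m$sections$point_ids[[i]]
    own <- if (m$sections$label[i] == "soma") ids else ids[-1]
    pts$type[match(own, pts$id)] <- label_to_swc_type(m$sections$label[i])
  }
  txt <- sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                 pts$id, pts$type, pts$x, pts$y, pts$z, pts$radius, pts$parent)
  writeLines(c("# generated by golgicell", txt), path)
  invisible(path)
}

#' Classify sections into soma, axon, AIS, basal and apical dendrites
#'
#' Dendritic sections whose centroid lies beyond the Purkinje-cell-layer
#' boundary along the y axis (toward the molecular layer) are relabeled
#' apical; the rest basal. The first `ais_length` micrometers of axon path
#' leaving the soma (or a basal dendrite, where the axon stems from one) are
#' relabeled AIS, splitting the proximal axon section if necessary.
#'
#' @param m A `goc_morphology`.
#' @param pc_layer_y Boundary y coordinate (um). Default: soma centroid
#'   y + 20 um.
#' @param ais_length Length of the axon initial segment, um (default 25).
#' @return The relabeled `goc_morphology`.
#' @export
classify_sections <- function(m, pc_layer_y = NULL, ais_length = 25) {
  stopifnot(inherits(m, "goc_morphology"))
  soma_row <- which(m$sections$label == "soma")
  soma_pts <- section_points(m, soma_row)
  if (is.null(pc_layer_y)) pc_layer_y <- mean(soma_pts$y) + 20
  dend <- which(m$sections$label %in% c("basal_dendrite", "apical_dendrite"))
  for (i in dend) {
    p <- section_points(m, i)
    centroid_y <- mean(p$y[-1]) # skip attachment point
    m$sections$label[i] <- if (centroid_y > pc_layer_y) "apical_dendrite" else "basal_dendrite"
  }
  # AIS: walk the axon from its origin, relabeling the first ais_length um
  m <- mark_ais(m, ais_length)
  if (!any(m$sections$label %in% c("axon", "AIS"))) {
    warn("morphology has no axon section; model valid for somatic protocols only")
  }
  m$compartments <- NULL # labels changed; must rediscretize
  m
}

mark_ais <- function(m, ais_length) {
  if (ais_length <= 0) return(m)
  # proximal axon sections: axon sections whose parent is not an axon/AIS
  is_axonish <- m$sections$label %in% c("axon", "AIS")
  m$sections$label[m$sections$label == "AIS"] <- "axon"
  prox <- which(m$sections$label == "axon" &
                  (is.na(m$sections$parent_section) |
                     !(m$sections$label[m$sections$parent_section] %in% "axon")))
  for (start in prox) {
    remaining <- ais_length
    cur <- start
    while (remaining > 1e-9 && !is.na(cur) && m$sections$label[cur] == "axon") {
      len <- section_length(m, cur)
      if (len <= remaining + 1e-12) {
        m$sections$label[cur] <- "AIS"
        remaining <- remaining - len
        kids <- which(m$sections$parent_section == cur & m$sections$label == "axon")
        cur <- if (length(kids) == 1) kids else NA_integer_
      } else {
        m <- split_section(m, cur, remaining)
        m$sections$label[cur] <- "AIS"
        remaining <- 0
      }
    }
  }
  m
}

# Split section `sec` at path distance `at` (um) from its proximal end by
# inserting an interpolated point; the distal part becomes a new section.
split_section <- function(m, sec, at) {
  p <- section_points(m, sec)
  seg <- sqrt(diff(p$x)^2 + diff(p$y)^2 + diff(p$z)^2)
  cum <- c(0, cumsum(seg))
  below <- which(cum < at - 1e-12)
  k <- if (length(below) > 0) max(below) else 1L # segment k: points k to k+1
  frac <- (at - cum[k]) / seg[k]
  new_id <- max(m$points$id) + 1L
  interp <- function(a, b) a + frac * (b - a)
  if (frac > 1e-9 && frac < 1 - 1e-9) {
    newpt <- tibble(
      id = new_id, type = m$points$type[match(p$id[k], m$points$id)],
      x = interp(p$x[k], p$x[k + 1]), y = interp(p$y[k], p$y[k + 1]),
      z = interp(p$z[k], p$z[k + 1]),
      radius = interp(p$radius[k], p$radius[k + 1]),
      parent = p$id[k]
    )
    m$points <- rbind(m$points, newpt)
    m$points$parent[m$points$id == p$id[k + 1]] <- new_id
    prox_ids <- c(p$id[1:k], new_id)
    dist_ids <- c(new_id, p$id[(k + 1):nrow(p)])
  } else {
    cut <- if (frac <= 1e-9) k else k + 1
    prox_ids <- p$id[1:cut]
    dist_ids <- p$id[cut:nrow(p)]
  }
  new_sec <- nrow(m$sections) + 1L
  m$sections$point_ids[[sec]] <- prox_ids
  m$sections <- rbind(
    m$sections,
    tibble(section_id = new_sec, label = m$sections$label[sec],
           parent_section = sec, point_ids = list(dist_ids))
  )
  # reparent children of sec that attached distally
  kids <- which(m$sections$parent_section == sec)
  kids <- setdiff(kids, new_sec)
  for (kk in kids) {
    att <- m$sections$point_ids[[kk]][1]
    if (att %in% dist_ids[-1] || att == dist_ids[length(dist_ids)]) {
      m$sections$parent_section[kk] <- new_sec
    }
  }
  m
}

#' Discretize a morphology into cylindrical compartments
#'
#' Each section is cut into an odd number of equal-length compartments no
#' longer than `max_seg_length`, so that voltage is sampled at the section
#' center (standard second-order accuracy). Compartment diameters are chosen
#' so the summed cylinder areas reproduce the section's membrane area
#' exactly.
#'
#' @param m A `goc_morphology`.
#' @param max_seg_length Maximum compartment length, um.
#' @return The morphology with a `compartments` tibble: compartment id,
#'   section, label, length and diameter (um), membrane area (cm^2), path
#'   distance of the compartment center from the soma center (um), parent
#'   compartment and axial resistance to it (MOhm).
#' @export
discretize <- function(m, max_seg_length = 20) {
  stopifnot(inherits(m, "goc_morphology"), max_seg_length > 0)
  secs <- m$sections
  nsec <- nrow(secs)
  ord <- order(is.na(secs$parent_section), decreasing = TRUE) # root first
  ord <- tree_order(secs$parent_section)
  comp <- list()
  first_comp <- integer(nsec); last_comp <- integer(nsec)
  sec_dist0 <- numeric(nsec) # path distance of section proximal end from soma center
  next_id <- 0L
  for (s in ord) {
    p <- section_points(m, s)
    if (nrow(p) < 2) {
      # single-point soma: sphere -> one compartment, cylinder with
      # diameter = length = sphere diameter (equal area convention)
      d <- 2 * p$radius[1]
      n <- 1L
      lens <- d
      diams <- d
      ri_half <- ra_mohm(lens / 2, diams, 122) # placeholder Ra; rescaled at assembly
      centers <- d / 2
      L <- d
    } else {
      seg <- sqrt(diff(p$x)^2 + diff(p$y)^2 + diff(p$z)^2)
      L <- sum(seg)
      n <- as.integer(ceiling(L / max_seg_length))
      if (n %% 2L == 0L) n <- n + 1L
      cuts <- seq(0, L, length.out = n + 1)
      cum <- c(0, cumsum(seg))
      dia_at <- function(x) {
        # linear interpolation of diameter along the path
        stats::approx(cum, 2 * p$radius, xout = pmin(pmax(x, 0), L),
                      rule = 2)$y
      }
      lens <- diff(cuts)
      # mean diameter over each span conserves total cylindrical area
      diams <- vapply(seq_len(n), function(i) {
        xs <- c(cuts[i], cum[cum > cuts[i] & cum < cuts[i + 1]], cuts[i + 1])
        ds <- dia_at(xs)
        sum((ds[-1] + ds[-length(ds)]) / 2 * diff(xs)) / lens[i]
      }, numeric(1))
      centers <- (cuts[-1] + cuts[-(n + 1)]) / 2
    }
    parent_sec <- secs$parent_section[s]
    ids <- next_id + seq_len(n)
    next_id <- next_id + n
    first_comp[s] <- ids[1]; last_comp[s] <- ids[n]
    if (is.na(parent_sec)) {
      par0 <- NA_integer_
      sec_dist0[s] <- if (secs$label[s] == "soma") -L / 2 else 0
    } else if (secs$label[parent_sec] == "soma") {
      # attach to the soma compartment nearest the attachment point
      par0 <- soma_attach_comp(m, comp, parent_sec, first_comp, last_comp, s)
      sec_dist0[s] <- 0
    } else {
      par0 <- last_comp[parent_sec]
      sec_dist0[s] <- sec_dist0[parent_sec] + section_length(m, parent_sec)
    }
    parents <- c(par0, ids[-n])
    comp[[s]] <- tibble(
      comp_id = ids, section_id = s, label = secs$label[s],
      length_um = lens, diam_um = diams,
      area_cm2 = pi * diams * lens * 1e-8,
      path_dist_um = sec_dist0[s] + centers,
      parent_comp = parents
    )
  }
  comps <- dplyr::bind_rows(comp[order(vapply(comp, function(x) x$comp_id[1], numeric(1)))])
  comps <- comps[order(comps$comp_id), ]
  # axial resistance placeholder: geometry factor L/(pi r^2) summed over the
  # two half compartments; multiplied by Ra at assembly time
  geom <- comps$length_um / 2 / (pi * (comps$diam_um / 2)^2) # um^-1
  gpar <- comps$parent_comp
  comps$ri_geom <- geom + ifelse(is.na(gpar), 0, geom[match(gpar, comps$comp_id)])
  m$compartments <- comps
  m$max_seg_length <- max_seg_length
  m
}

# topological order of sections (parents first)
tree_order <- function(parent) {
  n <- length(parent)
  ord <- integer(0)
  placed <- logical(n)
  repeat {
    ready <- which(!placed & (is.na(parent) | placed[ifelse(is.na(parent), 1L, parent)]))
    if (length(ready) == 0) break
    ord <- c(ord, ready)
    placed[ready] <- TRUE
  }
  if (length(ord) != n) abort("section tree is not connected")
  ord
}

soma_attach_comp <- function(m, comp, soma_sec, first_comp, last_comp, child_sec) {
  # nearest soma compartment to the attachment point, by position along soma
  att_id <- m$sections$point_ids[[child_sec]][1]
  p <- section_points(m, soma_sec)
  if (nrow(p) < 2) return(first_comp[soma_sec])
  seg <- sqrt(diff(p$x)^2 + diff(p$y)^2 + diff(p$z)^2)
  cum <- c(0, cumsum(seg))
  pos <- cum[match(att_id, p$id)]
  if (is.na(pos)) pos <- sum(seg) / 2
  soma_comps <- comp[[soma_sec]]
  centers <- cumsum(soma_comps$length_um) - soma_comps$length_um / 2
  soma_comps$comp_id[which.min(abs(centers - pos))]
}

# axial resistance of a cylinder, MOhm (len, diam in um; ra in Ohm cm)
ra_mohm <- function(len_um, diam_um, ra) {
  ra * (len_um * 1e-4) / (pi * (diam_um * 1e-4 / 2)^2) / 1e6
}

#' Compartment table of a discretized morphology
#'
#' @param m A discretized `goc_morphology`.
#' @return The `compartments` tibble (see [discretize()]).
#' @export
compartment_table <- function(m) {
  if (is.null(m$compartments)) abort("morphology is not discretized; call discretize()")
  m$compartments
}

#' Parameters for the surrogate morphology generator
#'
#' Defaults emulate the published mouse Golgi cell reconstructions: a soma of
#' ~20 um diameter in the granular layer, basal dendrites spreading laterally
#' below the Purkinje-cell layer, apical dendrites ascending into the
#' molecular layer, and an axon with an initial segment stemming either from
#' the soma or from a basal dendrite.
#'
#' @param soma_diam_um Soma diameter.
#' @param n_basal,n_apical Number of primary basal/apical dendrites.
#' @param basal_length_um,apical_length_um Mean primary branch path length.
#' @param basal_diam_um,apical_diam_um Proximal dendrite diameter (tapering
#'   to 60% at the tip).
#' @param n_branch Daughter branches per primary dendrite.
#' @param axon_length_um,axon_diam_um Axon geometry.
#' @param ais_length_um,ais_diam_um Axon initial segment geometry; the
#'   initial segment is thicker than the distal axon and carries the HCN,
#'   M-current, Kca1.1 and Cav2.2 complement of the spike initiation zone.
#' @param axon_from_soma Probability that the axon stems from the soma
#'   rather than a basal dendrite (the reconstructions split 4/4).
#' @param length_cv Coefficient of variation of branch lengths.
#' @return A named list of generator parameters.
#' @export
surrogate_params <- function(soma_diam_um = 20,
                             n_basal = 5, n_apical = 2,
                             basal_length_um = 70, apical_length_um = 160,
                             basal_diam_um = 1.8, apical_diam_um = 1.5,
                             n_branch = 3,
                             axon_length_um = 400, axon_diam_um = 0.8,
                             ais_length_um = 25, ais_diam_um = 2.4,
                             axon_from_soma = 0.5,
                             length_cv = 0.15) {
  p <- as.list(environment())
  bad <- names(p)[vapply(p, function(v) !is.numeric(v) || length(v) != 1 || v < 0,
                         logical(1))]
  if (length(bad) > 0) {
    abort(paste0("invalid surrogate parameter: ", bad[1]))
  }
  if (p$axon_from_soma > 1) abort("invalid surrogate parameter: axon_from_soma")
  p
}

#' Generate a surrogate Golgi cell morphology
#'
#' Deterministic for a fixed seed. The surrogate stands in for the
#' NeuroMorpho reconstructions used to build the published models: soma at
#' the origin, basal dendrites in the granular layer (y < 20 um), apical
#' dendrites projecting into the molecular layer (y up to ~200 um), and an
#' axon descending into the granular layer whose first `ais_length_um`
#' micrometers form the AIS. Labels are assigned by construction and are
#' reproduced by [classify_sections()] with default settings.
#'
#' @param params Generator parameters from [surrogate_params()].
#' @param seed Integer seed.
#' @return A labeled `goc_morphology`.
#' @export
make_surrogate <- function(params = surrogate_params(), seed = 1) {
  if (!is.list(params)) abort("params must come from surrogate_params()")
  rng <- local_rng(seed)
  pts <- new.env()
  pts$df <- tibble(id = integer(), type = integer(), x = numeric(),
                   y = numeric(), z = numeric(), radius = numeric(),
                   parent = integer())
  add_pt <- function(type, x, y, z, r, parent) {
    id <- nrow(pts$df) + 1L
    pts$df <- rbind(pts$df, tibble(id = id, type = as.integer(type),
                                   x = x, y = y, z = z, radius = r,
                                   parent = as.integer(parent)))
    id
  }
  rs <- params$soma_diam_um / 2
  s1 <- add_pt(1, 0, -rs, 0, rs, -1L)
  s2 <- add_pt(1, 0, 0, 0, rs, s1)
  s3 <- add_pt(1, 0, rs, 0, rs, s2)
  # grow a tapering dendrite as a polyline toward direction dir
  grow_branch <- function(type, from_id, origin, dir, len, d0, d1, npts = 5) {
    prev <- from_id
    pos <- origin
    step <- len / npts
    for (i in seq_len(npts)) {
      dirn <- dir + rng$norm(3) * 0.12
      dirn <- dirn / sqrt(sum(dirn^2))
      pos <- pos + dirn * step
      r <- (d0 + (d1 - d0) * i / npts) / 2
      prev <- add_pt(type, pos[1], pos[2], pos[3], r, prev)
    }
    list(id = prev, pos = pos, dir = dir)
  }
  rand_len <- function(mean) max(mean * (1 + rng$norm(1) * params$length_cv), mean * 0.4)
  basal_tips <- list()
  for (b in seq_len(params$n_basal)) {
    ang <- 2 * pi * (b - 0.5) / params$n_basal
    dir <- c(cos(ang) * 0.9, -0.35, sin(ang) * 0.9)
    dir <- dir / sqrt(sum(dir^2))
    tip <- grow_branch(3, s2, c(0, 0, 0), dir, rand_len(params$basal_length_um),
                       params$basal_diam_um, params$basal_diam_um * 0.75)
    for (k in seq_len(params$n_branch)) {
      spread <- c(rng$norm(1) * 0.5, -0.1 + rng$norm(1) * 0.2, rng$norm(1) * 0.5)
      dird <- tip$dir + spread
      dird <- dird / sqrt(sum(dird^2))
      bt <- grow_branch(3, tip$id, tip$pos, dird,
                        rand_len(params$basal_length_um * 0.7),
                        params$basal_diam_um * 0.75, params$basal_diam_um * 0.45)
      basal_tips[[length(basal_tips) + 1]] <- bt
    }
    basal_tips[[length(basal_tips) + 1]] <- tip
  }
  for (a in seq_len(params$n_apical)) {
    ang <- 2 * pi * (a - 0.25) / params$n_apical
    dir <- c(cos(ang) * 0.45, 1, sin(ang) * 0.45)
    dir <- dir / sqrt(sum(dir^2))
    tip <- grow_branch(4, s3, c(0, rs, 0), dir, rand_len(params$apical_length_um),
                       params$apical_diam_um, params$apical_diam_um * 0.7)
    for (k in seq_len(params$n_branch)) {
      spread <- c(rng$norm(1) * 0.4, 0.4 + rng$norm(1) * 0.2, rng$norm(1) * 0.4)
      dird <- tip$dir + spread
      dird <- dird / sqrt(sum(dird^2))
      grow_branch(4, tip$id, tip$pos, dird,
                  rand_len(params$apical_length_um * 0.8),
                  params$apical_diam_um * 0.7, params$apical_diam_um * 0.4)
    }
  }
  # axon: from soma or from the first basal dendrite trunk
  from_soma <- rng$unif(1) < params$axon_from_soma
  if (from_soma || length(basal_tips) == 0) {
    ax_from <- s1; ax_origin <- c(0, -rs, 0)
  } else {
    bt <- basal_tips[[length(basal_tips)]] # a primary basal tip
    ax_from <- bt$id; ax_origin <- bt$pos
  }
    # thick tapering initial segment, then thin distal axon
  ax_dir <- c(0.15, -1, 0.05) / sqrt(1 + 0.15^2 + 0.05^2)
  ais_tip <- grow_branch(2, ax_from, ax_origin, ax_dir,
                         params$ais_length_um, params$ais_diam_um,
                         params$ais_diam_um * 0.8, npts = 2)
  grow_branch(2, ais_tip$id, ais_tip$pos, ax_dir,
              params$axon_length_um - params$ais_length_um,
              params$axon_diam_um, params$axon_diam_um, npts = 7)
  m <- new_morphology(pts$df, provenance = list(source = "surrogate", seed = seed,
                                                params = params))
  classify_sections(m, pc_layer_y = 20, ais_length = params$ais_length_um)
}

# small deterministic RNG wrapper that does not touch the global stream
local_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    s
  })
  draw <- function(fn, n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- fn(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    out
  }
  list(norm = function(n) draw(stats::rnorm, n),
       unif = function(n) draw(stats::runif, n))
}
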