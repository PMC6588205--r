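#' Construct a vascular network
#'
#' A `vascular_network` is the spatial-graph substrate for every computation
#' in the package: a set of nodes with 3-D coordinates (micron) joined by
#' vessel segments carrying a diameter and a (possibly tortuous) centreline
#' length. Degree-1 nodes form the network boundary, where flow enters,
#' leaves, or dead-ends; all other nodes are interior junctions at which
#' flux is conserved.
#'
#' @param nodes A data frame with columns `id`, `x`, `y`, `z` (micron).
#' @param segments A data frame with columns `id`, `from`, `to`, `diameter`,
#'   `length` (micron). `from`/`to` reference `nodes$id`; `length` is the
#'   centreline length and must be at least the Euclidean chord between the
#'   endpoints (up to a small rounding slack).
#' @param validate If `TRUE` (default) run the structural invariant checks.
#' @return An object of class `vascular_network`: a list with tibbles
#'   `nodes` (ids remapped to a contiguous 1..n index, original ids kept in
#'   `orig_id`) and `segments`, plus `units = "um"`.
#' @export
vascular_network <- function(nodes, segments, validate = TRUE) {
  nodes <- tibble::as_tibble(nodes)
  segments <- tibble::as_tibble(segments)
  need_n <- c("id", "x", "y", "z")
  need_s <- c("id", "from", "to", "diameter", "length")
  if (!all(need_n %in% names(nodes))) {
    stop("nodes must have columns ", paste(need_n, collapse = ", "))
  }
  if (!all(need_s %in% names(segments))) {
    stop("segments must have columns ", paste(need_s, collapse = ", "))
  }
  if (nrow(nodes) == 0L) stop("network has no nodes")

  # remap node ids to contiguous internal index
  idx <- match(nodes$id, nodes$id)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids in node table")
  from_i <- match(segments$from, nodes$id)
  to_i <- match(segments$to, nodes$id)
  if (validate) {
    bad <- which(is.na(from_i) | is.na(to_i))
    if (length(bad)) {
      stop("segment record(s) ", paste(utils::head(segments$id[bad], 5L), collapse = ", "),
           " reference node ids absent from the node table")
    }
    if (any(segments$from == segments$to)) {
      stop("segment(s) ", paste(segments$id[segments$from == segments$to], collapse = ", "),
           " are self-loops (identical endpoints)")
    }
    if (any(segments$diameter <= 0)) stop("all segment diameters must be > 0")
    if (any(segments$length <= 0)) stop("all segment lengths must be > 0")
    chord <- sqrt((nodes$x[from_i] - nodes$x[to_i])^2 +
                  (nodes$y[from_i] - nodes$y[to_i])^2 +
                  (nodes$z[from_i] - nodes$z[to_i])^2)
    # centreline length may exceed the chord (tortuosity) but never undercut it
    if (any(segments$length < chord * (1 - 1e-6) - 1e-9)) {
      stop("segment length below Euclidean endpoint distance; lengths are centreline lengths")
    }
  }
  net <- structure(
    list(
      nodes = tibble::tibble(
        id = seq_len(nrow(nodes)), orig_id = nodes$id,
        x = as.numeric(nodes$x), y = as.numeric(nodes$y), z = as.numeric(nodes$z)
      ),
      segments = tibble::tibble(
        id = seq_len(nrow(segments)), orig_id = segments$id,
        from = from_i, to = to_i,
        diameter = as.numeric(segments$diameter),
        length = as.numeric(segments$length)
      ),
      units = "um"
    ),
    class = "vascular_network"
  )
  net
}

#' @method print vascular_network
#' @export
print.vascular_network <- function(x, ...) {
  cat("<vascular_network> ", nrow(x$nodes), " nodes, ", nrow(x$segments),
      " segments, ", length(boundary_nodes(x)), " boundary nodes [um]\n", sep = "")
  invisible(x)
}

#' Node degrees of a vascular network
#' @param network A `vascular_network`.
#' @return Integer vector of segment counts incident to each node.
#' @export
node_degree <- function(network) {
  tabulate(c(network$segments$from, network$segments$to), nbins = nrow(network$nodes))
}

#' Boundary and interior node sets
#'
#' Boundary nodes are exactly the degree-1 nodes: terminals where a pressure
#' or flux condition must be supplied or estimated. All remaining nodes are
#' interior junctions.
#'
#' @param network A `vascular_network`.
#' @return Integer vector of node ids.
#' @export
boundary_nodes <- function(network) which(node_degree(network) == 1L)

#' @rdname boundary_nodes
#' @export
interior_nodes <- function(network) which(node_degree(network) != 1L)

#' Node coordinate matrix
#' @param network A `vascular_network`.
#' @return n x 3 numeric matrix of positions (micron).
#' @export
node_coords <- function(network) {
  cbind(x = network$nodes$x, y = network$nodes$y, z = network$nodes$z)
}

#' Read a vascular network from disk
#'
#' Two dialects are supported. `csv`: `path` is a directory holding
#' `nodes.csv` (`id,x,y,z`) and `segments.csv` (`id,from,to,diameter,length`),
#' both with a `# units: um` comment header. `json`: `path` is a single file
#' with top-level fields `units`, `nodes`, `segments`.
#'
#' @param path Directory (csv dialect) or file (json dialect).
#' @param dialect `"csv"` or `"json"`.
#' @return A validated [vascular_network()].
#' @export
read_network <- function(path, dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    nf <- file.path(path, "nodes.csv")
    sf <- file.path(path, "segments.csv")
    for (f in c(nf, sf)) if (!file.exists(f)) stop("file not found: ", f)
    nodes <- utils::read.csv(nf, comment.char = "#")
    segments <- utils::read.csv(sf, comment.char = "#")
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$nodes) || is.null(obj$segments)) {
      stop("malformed json network file: missing 'nodes' or 'segments' in ", path)
    }
    nodes <- obj$nodes
    segments <- obj$segments
  }
  vascular_network(nodes, segments)
}

#' Write a vascular network to disk
#'
#' Inverse of [read_network()]: a csv/json round trip reproduces every field
#' bit-exactly (original ids are restored on write).
#'
#' @param network A `vascular_network`.
#' @param path Directory (csv) or file (json); csv directories are created.
#' @param dialect `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  if (nrow(network$segments) == 0L) stop("refusing to write an empty network")
  nodes <- data.frame(id = network$nodes$orig_id, x = network$nodes$x,
                      y = network$nodes$y, z = network$nodes$z)
  segments <- data.frame(
    id = network$segments$orig_id,
    from = network$nodes$orig_id[network$segments$from],
    to = network$nodes$orig_id[network$segments$to],
    diameter = network$segments$diameter, length = network$segments$length
  )
  if (dialect == "csv") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("nodes", "segments")) {
      f <- file.path(path, paste0(nm, ".csv"))
      con <- file(f, "w")
      writeLines("# units: um", con)
      utils::write.csv(get(nm), con, row.names = FALSE, quote = FALSE)
      close(con)
    }
  } else {
    jsonlite::write_json(
      list(units = "um", nodes = nodes, segments = segments),
      path, dataframe = "columns", auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' Validate and clean a vascular network
#'
#' Removes zero-length segments, merges nodes closer than `tol` (micron),
#' drops segments collapsed by the merge, and reports connected components.
#' With `policy = "keep_largest"` only the largest component is retained.
#'
#' @param network A `vascular_network`.
#' @param tol Node-merge position tolerance in micron (default `1e-3`, below
#'   imaging resolution, above float noise).
#' @param policy `"keep_all"` or `"keep_largest"` for disconnected networks.
#' @return A list with elements `network` (cleaned) and `report` (tibble of
#'   modifications: one row per action with `action`, `count`), plus
#'   `n_components` as an attribute of the report.
#' @export
validate_and_clean <- function(network, tol = 1e-3, policy = c("keep_all", "keep_largest")) {
  policy <- match.arg(policy)
  nodes <- network$nodes
  segs <- network$segments
  report <- tibble::tibble(action = character(), count = integer())

  # merge duplicate nodes within tolerance (grid hash on tol-sized cells)
  key <- paste(round(nodes$x / tol), round(nodes$y / tol), round(nodes$z / tol))
  grp <- match(key, key)
  n_merged <- sum(grp != seq_along(grp))
  if (n_merged > 0L) {
    segs$from <- grp[segs$from]
    segs$to <- grp[segs$to]
    keep <- sort(unique(grp))
    remap <- match(seq_len(nrow(nodes)), keep)
    nodes <- nodes[keep, ]
    segs$from <- remap[segs$from]
    segs$to <- remap[segs$to]
    report <- dplyr::bind_rows(report, tibble::tibble(action = "merged_duplicate_nodes", count = n_merged))
  }

  drop0 <- segs$length <= 0 | segs$from == segs$to
  if (any(drop0)) {
    segs <- segs[!drop0, ]
    report <- dplyr::bind_rows(report, tibble::tibble(action = "removed_zero_length_segments",
                                                      count = sum(drop0)))
  }
  if (nrow(segs) == 0L) stop("network empty after cleaning")

  g <- igraph::graph_from_edgelist(cbind(segs$from, segs$to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(nodes) - igraph::vcount(g)))
  comp <- igraph::components(g)
  if (policy == "keep_largest" && comp$no > 1L) {
    main <- which.max(comp$csize)
    keep_nodes <- which(comp$membership == main)
    keep_segs <- segs$from %in% keep_nodes & segs$to %in% keep_nodes
    dropped <- sum(!keep_segs)
    remap <- match(seq_len(nrow(nodes)), keep_nodes)
    segs <- segs[keep_segs, ]
    segs$from <- remap[segs$from]
    segs$to <- remap[segs$to]
    nodes <- nodes[keep_nodes, ]
    report <- dplyr::bind_rows(report, tibble::tibble(action = "removed_minor_component_segments",
                                                      count = dropped))
    comp <- list(no = 1L)
  }
  # drop isolated nodes left behind by segment removal
  used <- sort(unique(c(segs$from, segs$to)))
  if (length(used) < nrow(nodes)) {
    n_iso <- nrow(nodes) - length(used)
    remap <- match(seq_len(nrow(nodes)), used)
    nodes <- nodes[used, ]
    segs$from <- remap[segs$from]
    segs$to <- remap[segs$to]
    if (n_merged > 0L || any(drop0) || policy == "keep_largest") {
      report <- dplyr::bind_rows(report, tibble::tibble(action = "removed_isolated_nodes",
                                                        count = n_iso))
    }
  }
  out <- vascular_network(
    data.frame(id = seq_len(nrow(nodes)), x = nodes$x, y = nodes$y, z = nodes$z),
    data.frame(id = seq_len(nrow(segs)), from = segs$from, to = segs$to,
               diameter = segs$diameter, length = segs$length)
  )
  # preserve original ids when nothing changed
  if (nrow(report) == 0L) out <- network
  attr(report, "n_components") <- comp$no
  list(network = out, report = report)
}

#' Branching-vessel decomposition
#'
#' Collapses chains of degree-2 nodes so that each "branching vessel" runs
#' between two junction/boundary nodes; every segment belongs to exactly one
#' branch. Pure cycles of degree-2 nodes are returned as single closed
#' branches.
#'
#' @param network A `vascular_network`.
#' @return A tibble with one row per branch: `branch`, `n_segments`,
#'   `length` (summed centreline length, micron), `mean_diameter`
#'   (length-weighted, micron).
#' @export
network_branches <- function(network) {
  segs <- network$segments
  deg <- node_degree(network)
  # incident segment lists
  inc <- vector("list", nrow(network$nodes))
  for (j in seq_len(nrow(segs))) {
    inc[[segs$from[j]]] <- c(inc[[segs$from[j]]], j)
    inc[[segs$to[j]]] <- c(inc[[segs$to[j]]], j)
  }
  visited <- logical(nrow(segs))
  branch_id <- integer(nrow(segs))
  nb <- 0L
  walk <- function(seg, from_node) {
    # follow a chain of degree-2 nodes starting along `seg` away from `from_node`
    chain <- integer(0)
    cur_seg <- seg
    cur_node <- from_node
    repeat {
      chain <- c(chain, cur_seg)
      nxt <- if (segs$from[cur_seg] == cur_node) segs$to[cur_seg] else segs$from[cur_seg]
      if (deg[nxt] != 2L) break
      cand <- setdiff(inc[[nxt]], cur_seg)
      if (length(cand) == 0L || visited[cand[1L]]) break
      cur_seg <- cand[1L]
      cur_node <- nxt
    }
    chain
  }
  anchors <- which(deg != 2L)
  for (a in anchors) {
    for (s in inc[[a]]) {
      if (!visited[s]) {
        ch <- walk(s, a)
        nb <- nb + 1L
        visited[ch] <- TRUE
        branch_id[ch] <- nb
      }
    }
  }
  # leftover pure cycles (all nodes degree 2)
  for (s in which(!visited)) {
    if (!visited[s]) {
      ch <- walk(s, segs$from[s])
      nb <- nb + 1L
      visited[ch] <- TRUE
      branch_id[ch] <- nb
    }
  }
  tibble::tibble(branch = branch_id, seg = segs$id,
                 length = segs$length, diameter = segs$diameter) |>
    dplyr::group_by(.data$branch) |>
    dplyr::summarise(
      n_segments = dplyr::n(),
      length = sum(.data$length),
      mean_diameter = sum(.data$diameter * .data$length) / sum(.data$length),
      .groups = "drop"
    )
}

#' Summary statistics of a vascular network
#'
#' Vessel volume is the summed cylinder volume `pi (d/2)^2 l`, vascular
#' density its percentage of the enclosing (hull) volume, and the vascular
#' surface area `S = sum(pi d l)` yields the surface-to-volume ratio `S/V`
#' reported in 1/cm. Branch lengths are measured over branching vessels
#' (chains of degree-2 nodes merged; see [network_branches()]).
#'
#' @param network A `vascular_network`.
#' @param hull_volume_cm3 Enclosing tissue volume in cm3. If `NULL`, the
#'   volume of the convex hull of the node cloud is used.
#' @return A one-row tibble: counts, mean/sd diameter (um), mean/sd
#'   branching-vessel length (um), bounding-box dimensions (mm), vessel
#'   volume (cm3), vascular density (%), surface area (cm2) and S/V (1/cm).
#' @export
network_statistics <- function(network, hull_volume_cm3 = NULL) {
  segs <- network$segments
  if (is.null(hull_volume_cm3)) {
    hull <- compute_hull(node_coords(network), subdivisions = 0L)
    hull_volume_cm3 <- hull$volume_cm3
  }
  stopifnot(hull_volume_cm3 > 0)
  um3_to_cm3 <- tf_units$um_to_cm^3
  vessel_volume_cm3 <- sum(pi * (segs$diameter / 2)^2 * segs$length) * um3_to_cm3
  surface_cm2 <- sum(pi * segs$diameter * segs$length) * tf_units$um_to_cm^2
  br <- network_branches(network)
  dims_mm <- apply(node_coords(network), 2L, function(v) diff(range(v))) / 1e3
  tibble::tibble(
    n_nodes = nrow(network$nodes),
    n_segments = nrow(segs),
    n_boundary_nodes = length(boundary_nodes(network)),
    mean_diameter_um = mean(segs$diameter),
    sd_diameter_um = stats::sd(segs$diameter),
    mean_branch_length_um = mean(br$length),
    sd_branch_length_um = stats::sd(br$length),
    dim_x_mm = dims_mm[[1]], dim_y_mm = dims_mm[[2]], dim_z_mm = dims_mm[[3]],
    vessel_volume_cm3 = vessel_volume_cm3,
    hull_volume_cm3 = hull_volume_cm3,
    vascular_density_pct = 100 * vessel_volume_cm3 / hull_volume_cm3,
    surface_area_cm2 = surface_cm2,
    surface_to_volume_cm = surface_cm2 / hull_volume_cm3
  )
}
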