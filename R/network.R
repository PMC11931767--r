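#' Generate a synthetic street network of microplaces
#'
#' Lays out a planar jittered-grid street network with exactly
#' `config$n_segments` street segments and `config$n_intersections`
#' intersections. Streets run along grid rows ("... St") and columns
#' ("... Ave"); a segment is one block of a street, and intersections are
#' placed preferentially at grid nodes shared by at least two generated
#' segments. Node positions are jittered so planar distances are
#' non-degenerate; grid spacing is 100 planar units. Output is deterministic
#' given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A tibble with class `microplace_network` and columns
#'   `id` (unique token), `kind` (`"segment"` or `"intersection"`),
#'   `label` (human-readable street / cross-street name), and `geometry`
#'   (list column: a 2-row coordinate matrix for segments, a 1-row matrix for
#'   intersections).
#' @export
#' @examples
#' net <- generate_network(synthetic_config(
#'   n_segments = 5, n_intersections = 3,
#'   year_start = 2007, year_end = 2008,
#'   annual_counts = c("2007" = 10), seed = 7
#' ))
#' dplyr::count(net, kind)
generate_network <- function(config) {
  validate_synthetic_config(config)
  n_seg <- config$n_segments
  n_int <- config$n_intersections
  if (n_seg + n_int < 1) {
    stop("network must contain at least one microplace", call. = FALSE)
  }

  # Smallest square grid with enough nodes for the intersections and enough
  # lattice edges (2k(k-1)) for the segments.
  k <- max(
    2L,
    ceiling(sqrt(max(1L, n_int))),
    ceiling((1 + sqrt(1 + 2 * n_seg)) / 2)
  )
  spacing <- 100

  set.seed(child_seed(config$seed, "network-layout"))
  node <- tidyr::expand_grid(row = seq_len(k), col = seq_len(k))
  node$x <- node$col * spacing + runif(nrow(node), -15, 15)
  node$y <- node$row * spacing + runif(nrow(node), -15, 15)
  node$idx <- seq_len(nrow(node))

  # Lattice edges in fixed order: along-row blocks first, then along-column.
  horiz <- dplyr::filter(node, .data$col < k)
  h_edges <- tibble::tibble(
    a = horiz$idx, b = horiz$idx + 1L,
    label = sprintf("%s blk %d", row_street(horiz$row), horiz$col)
  )
  vert <- dplyr::filter(node, .data$row < k)
  v_edges <- tibble::tibble(
    a = vert$idx, b = vert$idx + k,
    label = sprintf("%s blk %d", col_street(vert$col), vert$row)
  )
  edges <- dplyr::bind_rows(h_edges, v_edges)
  if (nrow(edges) < n_seg) {
    stop("internal error: grid too small for requested segments")
  }
  edges <- edges[seq_len(n_seg), , drop = FALSE]

  segments <- tibble::tibble(
    id = sprintf("seg-%06d", seq_len(n_seg)),
    kind = "segment",
    label = edges$label,
    geometry = purrr::map2(edges$a, edges$b, function(a, b) {
      rbind(c(node$x[a], node$y[a]), c(node$x[b], node$y[b]))
    })
  )

  # Intersections: nodes touched by >= 2 selected segments first, then the
  # remaining nodes in index order.
  deg <- tabulate(c(edges$a, edges$b), nbins = nrow(node))
  cand <- node$idx[order(deg < 2, node$idx)]
  if (n_int > length(cand)) {
    stop("internal error: grid too small for requested intersections")
  }
  picks <- cand[seq_len(n_int)]
  intersections <- tibble::tibble(
    id = sprintf("int-%06d", seq_len(n_int)),
    kind = "intersection",
    label = sprintf("%s & %s", row_street(node$row[picks]),
                    col_street(node$col[picks])),
    geometry = purrr::map(picks, function(i) {
      matrix(c(node$x[i], node$y[i]), nrow = 1)
    })
  )

  out <- dplyr::bind_rows(segments, intersections)
  if (n_int == 0) out <- segments
  if (n_seg == 0) out <- intersections
  class(out) <- c("microplace_network", class(out))
  out
}

row_street <- function(row) sprintf("S%d St", row)
col_street <- function(col) sprintf("A%d Ave", col)

validate_network <- function(network) {
  req <- c("id", "kind", "label", "geometry")
  if (!all(req %in% names(network))) {
    stop("network must have columns id, kind, label, geometry", call. = FALSE)
  }
  if (nrow(network) == 0) stop("network is empty", call. = FALSE)
  if (anyDuplicated(network$id)) {
    stop("network microplace ids must be unique", call. = FALSE)
  }
  bad <- purrr::map2_lgl(network$kind, network$geometry, function(k, g) {
    if (k == "segment") nrow(g) < 2 else nrow(g) != 1
  })
  if (any(bad)) {
    stop("segment geometry needs >= 2 vertices; intersections exactly 1",
         call. = FALSE)
  }
  invisible(network)
}

#' Tally microplaces by kind
#'
#' @param network A microplace network tibble.
#' @return A tibble with columns `kind`, `n`, `pct` (share rounded half-up to
#'   one decimal, matching the summary-table convention).
#' @export
counts_by_kind <- function(network) {
  validate_network(network)
  out <- dplyr::count(tibble::as_tibble(network), .data$kind)
  out$pct <- round_half_up(100 * out$n / sum(out$n), 1)
  out
}

# --- serialization ---------------------------------------------------------

coords_to_wkt <- function(kind, g) {
  pts <- apply(g, 1, function(p) sprintf("%.6f %.6f", p[1], p[2]))
  if (kind == "intersection") sprintf("POINT (%s)", pts[1])
  else sprintf("LINESTRING (%s)", paste(pts, collapse = ", "))
}

wkt_to_coords <- function(wkt) {
  body <- sub("^[A-Z]+ ?\\((.*)\\)$", "\\1", wkt)
  pts <- strsplit(strsplit(body, ",")[[1]], "[[:space:]]+")
  m <- do.call(rbind, lapply(pts, function(p) as.numeric(p[nzchar(p)])))
  unname(m)
}

#' Write or read a microplace network
#'
#' Networks round-trip through two plain-text formats: a GeoJSON
#' FeatureCollection (segments as LineString, intersections as Point, with
#' `kind` and `label` in `properties` and the microplace id as the feature
#' `id`) and a flat CSV with a WKT geometry column.
#'
#' @param network A microplace network tibble.
#' @param path File path.
#' @return Readers return the network tibble; writers return `path`
#'   invisibly.
#' @export
write_network_geojson <- function(network, path) {
  validate_network(network)
  features <- purrr::pmap(
    list(network$id, network$kind, network$label, network$geometry),
    function(id, kind, label, g) {
      geom <- if (kind == "intersection") {
        list(type = "Point", coordinates = round(as.numeric(g[1, ]), 6))
      } else {
        list(type = "LineString",
             coordinates = purrr::map(seq_len(nrow(g)),
                                      function(i) round(as.numeric(g[i, ]), 6)))
      }
      list(type = "Feature", id = id,
           properties = list(kind = kind, label = label),
           geometry = geom)
    }
  )
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = 6
  )
  invisible(path)
}

#' @rdname write_network_geojson
#' @export
read_network_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  out <- purrr::map_dfr(fc$features, function(f) {
    tibble::tibble(
      id = f$id,
      kind = f$properties$kind,
      label = f$properties$label,
      geometry = list(
        if (f$geometry$type == "Point") {
          matrix(unlist(f$geometry$coordinates), nrow = 1)
        } else {
          do.call(rbind, lapply(f$geometry$coordinates, unlist))
        }
      )
    )
  })
  class(out) <- c("microplace_network", class(out))
  validate_network(out)
  out
}

#' @rdname write_network_geojson
#' @export
write_network_csv <- function(network, path) {
  validate_network(network)
  flat <- tibble::tibble(
    id = network$id, kind = network$kind, label = network$label,
    wkt = purrr::map2_chr(network$kind, network$geometry, coords_to_wkt)
  )
  readr::write_csv(flat, path)
  invisible(path)
}

#' @rdname write_network_geojson
#' @export
read_network_csv <- function(path) {
  flat <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  out <- tibble::tibble(
    id = flat$id, kind = flat$kind, label = flat$label,
    geometry = purrr::map(flat$wkt, wkt_to_coords)
  )
  class(out) <- c("microplace_network", class(out))
  validate_network(out)
  out
}
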