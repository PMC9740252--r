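# Morphometry of tight-junction strand networks annotated on freeze-fracture
# replicas. The input is vectorised annotation (polylines in nm), not raw EM
# images: strand tracing is done by the annotator (or by the synthetic
# generator); this module implements the measurement geometry.
#
# Grid construction: vertical grid lines are placed at fixed intervals
# (default 200 nm) along the most apical strand, each perpendicular to the
# local strand tangent (smoothed over a 400 nm window by default, so curved
# junctions are followed; a global orientation mode is available). Counts,
# depth and breaks are all derived from exact segment-line intersections, so
# all outputs are invariant under rigid motions of the network.

#' Tight-junction strand network
#'
#' @param strands List of strands; each strand is a list with fields `id`,
#'   `appearance` (`"particle"`, `"continuous"`, or `NA` when unannotated)
#'   and `segments`, a list of n x 2 matrices of (x, y) vertices in nm.
#'   Polyline interruptions between consecutive segments encode candidate
#'   breaks.
#' @param apical_id `id` of the most apical strand.
#' @return Object of class `strand_network`.
#' @export
strand_network <- function(strands, apical_id) {
  if (length(strands) < 1L) stop("need at least one strand", call. = FALSE)
  ids <- vapply(strands, function(s) s$id, numeric(1))
  if (anyDuplicated(ids)) stop("duplicate strand ids", call. = FALSE)
  if (!apical_id %in% ids) stop("`apical_id` not found", call. = FALSE)
  strands <- lapply(strands, function(s) {
    s$segments <- lapply(s$segments, function(seg) {
      seg <- as.matrix(seg)
      if (ncol(seg) != 2L || nrow(seg) < 2L) {
        stop("each segment must be an n x 2 matrix with n >= 2", call. = FALSE)
      }
      dimnames(seg) <- NULL
      seg
    })
    s
  })
  structure(list(strands = strands, apical_id = apical_id),
            class = "strand_network")
}

#' @export
print.strand_network <- function(x, ...) {
  cat(sprintf("<strand_network> %d strands, apical id %s\n",
              length(x$strands), format(x$apical_id)))
  invisible(x)
}

strand_by_id <- function(net, id) {
  ids <- vapply(net$strands, function(s) s$id, numeric(1))
  net$strands[[which(ids == id)]]
}

# Grid lines along the apical strand: positions every `interval` nm of arc
# length (starting at interval/2), direction = normal to the local tangent
# (averaged over `tangent_window` nm of arc) or to the global end-to-end
# direction. Returns a tibble (px, py, nx, ny) with n = unit line direction.
apical_grid_lines <- function(net, interval = 200, tangent_window = 400,
                              mode = c("local", "global")) {
  mode <- match.arg(mode)
  ap <- strand_by_id(net, net$apical_id)
  lines <- list()
  for (seg in ap$segments) {
    d <- diff(seg)
    seg_len <- sqrt(rowSums(d^2))
    L <- sum(seg_len)
    cum <- c(0, cumsum(seg_len))
    if (L < interval) {
      s_pos <- L / 2
      warning("apical strand segment shorter than one grid interval; ",
              "using a single grid line", call. = FALSE)
    } else {
      s_pos <- seq(interval / 2, L, by = interval)
    }
    gdir <- seg[nrow(seg), ] - seg[1, ]
    gdir <- gdir / sqrt(sum(gdir^2))
    for (s in s_pos) {
      i <- max(which(cum <= s + 1e-9)); i <- min(i, length(seg_len))
      t_loc <- (s - cum[i]) / seg_len[i]
      p <- seg[i, ] + t_loc * (seg[i + 1, ] - seg[i, ])
      tangent <- if (mode == "global") gdir else {
        lo <- s - tangent_window / 2; hi <- s + tangent_window / 2
        w <- pmax(0, pmin(cum[-1], hi) - pmax(cum[-length(cum)], lo))
        tv <- colSums(d / seg_len * w)
        if (sum(tv^2) == 0) gdir else tv / sqrt(sum(tv^2))
      }
      lines[[length(lines) + 1L]] <- c(px = p[1], py = p[2],
                                       nx = -tangent[2], ny = tangent[1])
    }
  }
  dplyr::bind_rows(lapply(lines, function(v) tibble::tibble(!!!as.list(v))))
}

# Signed positions (along the line direction n) at which a strand crosses
# the infinite line through (px, py) with direction (nx, ny). A strand
# crossed twice still counts once per distinct strand; all crossing
# positions are returned for depth measurements.
strand_crossings <- function(strand, px, py, nx, ny) {
  tx <- ny; ty <- -nx  # perpendicular to the grid line
  out <- numeric(0)
  for (seg in strand$segments) {
    s <- (seg[, 1] - px) * tx + (seg[, 2] - py) * ty
    n <- nrow(seg)
    cross <- which(s[-n] * s[-1] < 0 | (s[-n] == 0 & s[-1] != 0))
    if (any(s == 0)) out <- c(out, (seg[s == 0, 1] - px) * nx +
                                (seg[s == 0, 2] - py) * ny)
    for (i in cross) {
      u <- s[i] / (s[i] - s[i + 1])
      q <- seg[i, ] + u * (seg[i + 1, ] - seg[i, ])
      out <- c(out, (q[1] - px) * nx + (q[2] - py) * ny)
    }
  }
  out
}

#' Strand counts along perpendicular grid lines
#'
#' Counts, at every grid line, the number of distinct strands intersected,
#' and returns the per-line counts and their mean (the "number of horizontal
#' strands" of the meshwork).
#'
#' @param net A [strand_network()].
#' @param interval Grid-line spacing along the apical strand, nm
#'   (default 200).
#' @param tangent_window Arc window for the local tangent, nm (default 400).
#' @param mode `"local"` (default) or `"global"` grid-line orientation.
#' @return List of class `strand_counts`: `per_line` tibble (line, s
#'   position, count), `mean_strand_number`.
#' @export
strand_counts <- function(net, interval = 200, tangent_window = 400,
                          mode = c("local", "global")) {
  stopifnot(inherits(net, "strand_network"))
  grid <- apical_grid_lines(net, interval, tangent_window, match.arg(mode))
  counts <- vapply(seq_len(nrow(grid)), function(i) {
    sum(vapply(net$strands, function(st) {
      length(strand_crossings(st, grid$px[i], grid$py[i],
                              grid$nx[i], grid$ny[i])) > 0
    }, logical(1)))
  }, integer(1))
  structure(list(per_line = tibble::tibble(line = seq_along(counts),
                                           count = counts),
                 grid = grid,
                 mean_strand_number = mean(counts)),
            class = "strand_counts")
}

#' Meshwork depth
#'
#' Mean distance, measured along the grid-line direction, between the most
#' apical and the contra-apical strand crossing each grid line. A network
#' with a single strand has depth 0 by definition (with one strand no
#' meshwork extension exists); grid lines crossing fewer than two strands do
#' not contribute.
#'
#' @inheritParams strand_counts
#' @return Depth in nm (scalar).
#' @export
meshwork_depth <- function(net, interval = 200, tangent_window = 400,
                           mode = c("local", "global")) {
  stopifnot(inherits(net, "strand_network"))
  if (length(net$strands) == 1L) return(0)
  grid <- apical_grid_lines(net, interval, tangent_window, match.arg(mode))
  depths <- vapply(seq_len(nrow(grid)), function(i) {
    tt <- unlist(lapply(net$strands, function(st) {
      ts <- strand_crossings(st, grid$px[i], grid$py[i],
                             grid$nx[i], grid$ny[i])
      if (length(ts)) range(ts) else NULL
    }))
    if (length(tt) < 2L) return(NA_real_)
    max(tt) - min(tt)
  }, numeric(1))
  depths <- depths[is.finite(depths)]
  if (length(depths) == 0L) return(0)
  mean(depths)
}

#' Count strand breaks
#'
#' A break is a polyline interruption within a strand whose end-to-end
#' Euclidean gap is strictly greater than `min_gap` nm (default 20; a gap of
#' exactly 20 nm is not a break).
#'
#' @param net A [strand_network()].
#' @param min_gap Gap threshold in nm (default 20, strict inequality).
#' @return Integer number of breaks across all strands.
#' @export
detect_breaks <- function(net, min_gap = 20) {
  stopifnot(inherits(net, "strand_network"))
  total <- 0L
  for (st in net$strands) {
    k <- length(st$segments)
    if (k < 2L) next
    for (i in seq_len(k - 1L)) {
      a <- st$segments[[i]]
      b <- st$segments[[i + 1L]]
      gap <- sqrt(sum((b[1, ] - a[nrow(a), ])^2))
      if (gap > min_gap) total <- total + 1L
    }
  }
  total
}

#' Proportions of strand appearance classes
#'
#' Fraction of strands annotated as particle type versus continuous type.
#'
#' @param net A [strand_network()] with all strands labelled.
#' @return One-row tibble: `n_strands`, `proportion_particle`,
#'   `proportion_continuous` (sums to 1).
#' @export
appearance_proportions <- function(net) {
  stopifnot(inherits(net, "strand_network"))
  app <- vapply(net$strands, function(s) {
    a <- s$appearance
    if (is.null(a) || length(a) != 1L || is.na(a) || !nzchar(a)) NA_character_
    else a
  }, character(1))
  if (anyNA(app)) stop("all strands must be labelled particle or continuous",
                       call. = FALSE)
  if (!all(app %in% c("particle", "continuous"))) {
    stop("appearance labels must be 'particle' or 'continuous'", call. = FALSE)
  }
  tibble::tibble(
    n_strands = length(app),
    proportion_particle = mean(app == "particle"),
    proportion_continuous = mean(app == "continuous")
  )
}

#' Full morphometry of one strand network
#'
#' Convenience wrapper returning mean strand number, meshwork depth, break
#' count and appearance proportions as one row (the per-junction record of a
#' freeze-fracture analysis).
#'
#' @inheritParams strand_counts
#' @param min_gap Break gap threshold, nm.
#' @return One-row tibble.
#' @export
strand_morphometry <- function(net, interval = 200, tangent_window = 400,
                               min_gap = 20) {
  sc <- strand_counts(net, interval, tangent_window)
  dplyr::bind_cols(
    tibble::tibble(
      mean_strand_number = sc$mean_strand_number,
      depth_nm = meshwork_depth(net, interval, tangent_window),
      n_breaks = detect_breaks(net, min_gap)
    ),
    appearance_proportions(net)
  )
}

#' Read a strand-network annotation from JSON
#'
#' Format: `{"pixel_size_nm": s, "strands": [{"id": i, "appearance":
#' "particle"|"continuous", "segments": [[[x, y], ...], ...]}, ...],
#' "apical_id": i}`. Coordinates are multiplied by `pixel_size_nm` (default
#' 1, i.e. already in nm).
#'
#' @param path Path to the JSON file.
#' @return A [strand_network()].
#' @export
read_strand_json <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  s <- j$pixel_size_nm %||% 1
  strands <- lapply(j$strands, function(st) {
    list(id = st$id, appearance = st$appearance %||% NA_character_,
         segments = lapply(st$segments, function(seg) {
           do.call(rbind, lapply(seg, unlist)) * s
         }))
  })
  strand_network(strands, j$apical_id)
}

#' Write a strand network to JSON
#'
#' @param net A [strand_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_strand_json <- function(net, path) {
  j <- list(
    pixel_size_nm = 1,
    apical_id = net$apical_id,
    strands = lapply(net$strands, function(st) {
      list(id = st$id, appearance = st$appearance,
           segments = lapply(st$segments, function(seg) {
             apply(unname(seg), 1, as.list)
           }))
    })
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
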