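#' Construct an integer-coded land-cover grid
#'
#' A regular raster of land-cover class codes on a local metric
#' coordinate system. Column j of the matrix spans x in
#' `origin[1] + (j-1)*cellsize .. origin[1] + j*cellsize`; row i spans y
#' analogously (row 1 at the origin edge). Cell centers sit at the
#' half-cell offsets.
#'
#' @param codes integer matrix of land-cover class codes.
#' @param origin numeric length-2: coordinates of the grid's lower-left
#'   corner, in meters.
#' @param cellsize cell edge length in meters (100 for CORINE-style
#'   grids).
#' @return an object of class `land_grid`.
#' @export
land_cover_grid <- function(codes, origin = c(0, 0), cellsize = 100) {
  codes <- as.matrix(codes)
  if (!is.numeric(codes) || anyNA(codes)) {
    stop("codes must be a complete numeric matrix", call. = FALSE)
  }
  if (cellsize <= 0) stop("cellsize must be positive", call. = FALSE)
  structure(list(codes = codes, origin = as.numeric(origin),
                 cellsize = cellsize),
            class = "land_grid")
}

#' Read a land-cover grid from a plain-text matrix
#'
#' Whitespace-delimited integers, one grid row per line; row 1 of the
#' file is the top (highest y) row of the grid.
#'
#' @param path file path.
#' @param origin,cellsize as in [land_cover_grid()].
#' @return a `land_grid`.
#' @export
read_land_grid <- function(path, origin = c(0, 0), cellsize = 100) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  # file rows run top-down; grid rows run bottom-up
  land_cover_grid(m[rev(seq_len(nrow(m))), , drop = FALSE],
                  origin = origin, cellsize = cellsize)
}

#' @export
print.land_grid <- function(x, ...) {
  cat(sprintf("Land-cover grid: %d x %d cells of %g m, origin (%g, %g)\n",
              nrow(x$codes), ncol(x$codes), x$cellsize,
              x$origin[1], x$origin[2]))
  cat("codes:", paste(sort(unique(as.vector(x$codes))), collapse = " "), "\n")
  invisible(x)
}

#' Default CORINE-style reclassification map
#'
#' Maps CORINE level-3 class codes to `"urban"` (artificial surfaces,
#' codes 1xx) or `"rural"` (agricultural, forest and semi-natural,
#' wetlands, water bodies — codes 2xx-5xx). This packaged default is an
#' approximation of the published urban/rural reclassification and can
#' be overridden with any named vector or two-column (code, category)
#' data frame.
#'
#' @return named character vector: names are class codes, values the
#'   categories.
#' @export
default_reclass <- function() {
  codes <- c(111, 112, 121, 122, 123, 124, 131, 132, 133, 141, 142,
             211, 212, 213, 221, 222, 223, 231, 241, 242, 243, 244,
             311, 312, 313, 321, 322, 323, 324, 331, 332, 333, 334, 335,
             411, 412, 421, 422, 423, 511, 512, 521, 522, 523)
  cat <- ifelse(codes < 200, "urban", "rural")
  stats::setNames(cat, codes)
}

as_reclass <- function(reclass) {
  if (is.data.frame(reclass)) {
    reclass <- stats::setNames(as.character(reclass[[2]]),
                               reclass[[1]])
  }
  if (is.null(names(reclass))) {
    stop("reclass map must be named by land-cover code", call. = FALSE)
  }
  reclass
}

#' Read a reclassification map from a two-column delimited file
#'
#' @param path file with header columns `code` and `category`.
#' @param sep field separator.
#' @return named character vector usable as a reclass map.
#' @export
read_reclass <- function(path, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  stats::setNames(as.character(d$category), d$code)
}

cell_index <- function(center, grid) {
  j <- floor((center[1] - grid$origin[1]) / grid$cellsize) + 1
  i <- floor((center[2] - grid$origin[2]) / grid$cellsize) + 1
  c(i, j)
}

#' Land-cover codes in the neighborhood of a point
#'
#' Returns the codes of every cell whose center lies within `radius`
#' meters of the center of the cell containing `center`. With a 500 m
#' radius on a 100 m grid this is exactly the 81 lattice cells with
#' offsets dx, dy satisfying dx^2 + dy^2 <= 25.
#'
#' @param center numeric length-2 point (same metric coordinates as the
#'   grid).
#' @param grid a `land_grid`.
#' @param radius neighborhood radius in meters.
#' @return integer vector of cell codes, with attribute `truncated`
#'   set `TRUE` when part of the neighborhood fell outside the grid.
#' @export
neighborhood_cells <- function(center, grid, radius = 500) {
  stopifnot(inherits(grid, "land_grid"))
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  ij <- cell_index(center, grid)
  nr <- nrow(grid$codes); nc <- ncol(grid$codes)
  if (ij[1] < 1 || ij[1] > nr || ij[2] < 1 || ij[2] > nc) {
    stop("center lies outside the grid", call. = FALSE)
  }
  k <- floor(radius / grid$cellsize)
  off <- expand.grid(dx = -k:k, dy = -k:k)
  off <- off[(off$dx^2 + off$dy^2) * grid$cellsize^2 <= radius^2, ]
  ii <- ij[1] + off$dy
  jj <- ij[2] + off$dx
  inside <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
  codes <- grid$codes[cbind(ii[inside], jj[inside])]
  attr(codes, "truncated") <- !all(inside)
  codes
}

#' Classify a site as urban or rural from its land-cover neighborhood
#'
#' Counts urban- and rural-mapped cells among the neighborhood of the
#' site and labels the site by strict majority between the two
#' categories; `"other"` cells are excluded from the comparison and a
#' tie yields `"unclassified"`. Codes absent from the reclass map count
#' as `"other"`, with a warning.
#'
#' @param center,grid,radius as in [neighborhood_cells()].
#' @param reclass named vector or (code, category) data frame mapping
#'   codes to `"urban"`, `"rural"` or `"other"`; defaults to
#'   [default_reclass()].
#' @return list with `label` (`"urban"`, `"rural"` or
#'   `"unclassified"`), `n_urban`, `n_rural`, `n_other`, `n_cells`, and
#'   `truncated`.
#' @export
classify_site <- function(center, grid, reclass = default_reclass(),
                          radius = 500) {
  reclass <- as_reclass(reclass)
  codes <- neighborhood_cells(center, grid, radius)
  cat <- unname(reclass[as.character(codes)])
  if (anyNA(cat)) {
    warning("unmapped land-cover code(s) treated as \"other\": ",
            paste(unique(codes[is.na(cat)]), collapse = ", "),
            call. = FALSE)
    cat[is.na(cat)] <- "other"
  }
  n_urban <- sum(cat == "urban")
  n_rural <- sum(cat == "rural")
  label <- if (n_urban > n_rural) "urban"
           else if (n_rural > n_urban) "rural"
           else "unclassified"
  list(label = label, n_urban = n_urban, n_rural = n_rural,
       n_other = sum(cat == "other"), n_cells = length(codes),
       truncated = attr(codes, "truncated"))
}

#' Add a habitat column to death records from a land-cover grid
#'
#' Classifies each geolocated record by [classify_site()] at its
#' coordinates. Geographic coordinates must first be projected to the
#' grid's metric system; pass the projection as `project` — it is a
#' configuration concern, not hard-coded.
#'
#' @param records a `death_records` data frame.
#' @param grid a `land_grid`.
#' @param reclass reclass map, as in [classify_site()].
#' @param radius neighborhood radius in meters.
#' @param project function mapping (longitude, latitude) vectors to a
#'   two-column matrix of metric x, y; the default treats the stored
#'   coordinates as already metric (longitude = x, latitude = y).
#' @return the records with the `habitat` column filled in; records
#'   without coordinates keep `NA`.
#' @export
classify_records <- function(records, grid, reclass = default_reclass(),
                             radius = 500,
                             project = function(lon, lat) cbind(lon, lat)) {
  stopifnot(inherits(records, "death_records"))
  has_xy <- !is.na(records$longitude) & !is.na(records$latitude)
  xy <- project(records$longitude[has_xy], records$latitude[has_xy])
  labels <- vapply(seq_len(nrow(xy)), function(i) {
    classify_site(xy[i, ], grid, reclass, radius)$label
  }, character(1))
  records$habitat[has_xy] <- labels
  records
}
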