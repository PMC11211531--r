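# Binary water-sensitive-paper stain images: layout, renderer, plain-text
# portable-bitmap I/O, and the ground deposition map.

#' Three-area assessment layout on the ground plane
#'
#' The sheltered ground strip under the plant is the test area; equal-sized
#' strips on either side are the controls. Each rectangle is `width` across
#' (the x direction, matching the leaf-width direction) by `length` along
#' y; the three lie side by side along x, centred on the plant axis.
#'
#' @param width Area width (m); default 15 mm.
#' @param length Area length (m); default 30 mm (the bottom-leaf ground
#'   extent, 29.28 mm, rounded up).
#' @return A tibble with `area` (`test`, `control_left`, `control_right`),
#'   `xmin`, `xmax`, `ymin`, `ymax` (m).
#' @examples
#' area_layout()
#' @export
area_layout <- function(width = 15e-3, length = 30e-3) {
  check_positive(width, "width")
  check_positive(length, "length")
  tibble(
    area = c("control_left", "test", "control_right"),
    xmin = c(-1.5 * width, -0.5 * width, 0.5 * width),
    xmax = c(-0.5 * width, 0.5 * width, 1.5 * width),
    ymin = -length / 2, ymax = length / 2
  )
}

#' Binary stain image
#'
#' A logical pixel grid over the bounding box of an area layout: `TRUE`
#' pixels are stained. Pixel (row 1, col 1) sits at the (ymin, xmin)
#' corner; columns advance along x, rows along y.
#'
#' @param pixels Logical matrix (rows = y, cols = x).
#' @param resolution Pixel size (m/pixel).
#' @param layout An [area_layout()].
#' @param origin `c(x, y)` of the grid's lower-left corner (m).
#' @return A `stain_image` list.
#' @export
stain_image <- function(pixels, resolution, layout,
                        origin = c(min(layout$xmin), min(layout$ymin))) {
  check_positive(resolution, "resolution")
  stopifnot(is.matrix(pixels), is.logical(pixels))
  structure(list(pixels = pixels, resolution = resolution,
                 layout = layout, origin = origin),
            class = "stain_image")
}

#' @export
print.stain_image <- function(x, ...) {
  cat(sprintf("<stain_image> %d x %d px @ %.3g mm/px, %.1f%% stained\n",
              nrow(x$pixels), ncol(x$pixels), x$resolution * 1e3,
              100 * mean(x$pixels)))
  invisible(x)
}

# pixel window of a rectangle (clipped to the grid)
.area_window <- function(img, area) {
  area <- as.list(area)
  nx <- ncol(img$pixels); ny <- nrow(img$pixels)
  c0 <- floor((as.numeric(area$xmin) - img$origin[1]) / img$resolution) + 1
  c1 <- ceiling((as.numeric(area$xmax) - img$origin[1]) / img$resolution)
  r0 <- floor((as.numeric(area$ymin) - img$origin[2]) / img$resolution) + 1
  r1 <- ceiling((as.numeric(area$ymax) - img$origin[2]) / img$resolution)
  rows <- seq_len(ny); cols <- seq_len(nx)
  list(rows = rows[rows >= r0 & rows <= r1],
       cols = cols[cols >= c0 & cols <= c1])
}

# stamp a disk of stained pixels, clipped to a column/row window
.stamp_disk <- function(pixels, cx, cy, r_px, cols, rows) {
  ci <- round(cx); ri <- round(cy)
  cc <- intersect(seq.int(floor(ci - r_px), ceiling(ci + r_px)), cols)
  rr <- intersect(seq.int(floor(ri - r_px), ceiling(ri + r_px)), rows)
  if (length(cc) == 0 || length(rr) == 0) return(pixels)
  d2 <- outer((rr - cy)^2, (cc - cx)^2, "+")
  pixels[rr, cc] <- pixels[rr, cc] | (d2 <= r_px^2)
  pixels
}

#' Render a synthetic water-sensitive-paper image
#'
#' Two driving modes:
#'
#' * **Deposit-driven** (`deposits` given): stamps one stain disk per
#'   deposit at its ground position, with stain radius `spread_factor`
#'   times the droplet radius (a wet stain reads larger than the droplet).
#' * **Target-driven** (`targets` given): for each area of the layout,
#'   stamps randomly placed disks (clipped to the area) until the measured
#'   coverage approaches the target, then tops up with single-pixel
#'   speckle until the measured coverage is within half a pixel of the
#'   target — always within 0.01.
#'
#' The achieved coverages are stored in the `ground_truth` attribute.
#' Deterministic for a fixed seed.
#'
#' @param targets Named or ordered length-3 coverages
#'   (test, control_left, control_right), fractions in `[0, 1]`.
#' @param deposits Tibble with `x`, `y` (m) and optionally `radius` (m).
#' @param layout An [area_layout()].
#' @param resolution Pixel size (m/pixel).
#' @param seed Integer seed.
#' @param droplet_radius Droplet radius (m) used for stain size.
#' @param spread_factor Stain radius over droplet radius.
#' @return A [stain_image()] with attribute `ground_truth` (tibble:
#'   `area`, `target`, `achieved`).
#' @examples
#' img <- render_paper(targets = c(test = 0.16, control_left = 0.72,
#'                                 control_right = 0.68), seed = 1)
#' attr(img, "ground_truth")
#' @export
render_paper <- function(targets = NULL, deposits = NULL,
                         layout = area_layout(), resolution = 2.5e-4,
                         seed = 1, droplet_radius = 1e-3,
                         spread_factor = 2) {
  check_positive(resolution, "resolution")
  origin <- c(min(layout$xmin), min(layout$ymin))
  nx <- ceiling((max(layout$xmax) - origin[1]) / resolution)
  ny <- ceiling((max(layout$ymax) - origin[2]) / resolution)
  pixels <- matrix(FALSE, ny, nx)
  img <- stain_image(pixels, resolution, layout, origin)
  r_px <- spread_factor * droplet_radius / resolution

  if (!is.null(deposits) && nrow(deposits) > 0) {
    rad <- if ("radius" %in% names(deposits)) deposits$radius else droplet_radius
    for (k in seq_len(nrow(deposits))) {
      cx <- (deposits$x[k] - origin[1]) / resolution + 0.5
      cy <- (deposits$y[k] - origin[2]) / resolution + 0.5
      img$pixels <- .stamp_disk(img$pixels, cx, cy,
                                spread_factor * rad[min(k, length(rad))] / resolution,
                                seq_len(nx), seq_len(ny))
    }
  }

  gt <- NULL
  if (!is.null(targets)) {
    if (!is.null(names(targets))) {
      targets <- targets[c("test", "control_left", "control_right")]
    }
    targets <- unname(targets)
    if (any(!is.finite(targets)) || any(targets < 0) || any(targets > 1)) {
      stop_domain("target coverages must be fractions in [0, 1]")
    }
    areas <- c("test", "control_left", "control_right")
    achieved <- numeric(3)
    img$pixels <- with_seed(seed, {
      px <- img$pixels
      for (ai in seq_along(areas)) {
        a <- layout[layout$area == areas[ai], ]
        w <- .area_window(img, a)
        npix <- length(w$rows) * length(w$cols)
        disk_frac <- pi * r_px^2 / npix
        cov <- function() mean(px[w$rows, w$cols])
        guard <- 0
        while (cov() < targets[ai] - 1.5 * disk_frac && guard < 1e5) {
          px <- .stamp_disk(px,
                            runif(1, min(w$cols) - 0.5, max(w$cols) + 0.5),
                            runif(1, min(w$rows) - 0.5, max(w$rows) + 0.5),
                            r_px, w$cols, w$rows)
          guard <- guard + 1
        }
        # single-pixel speckle top-up to hit the target exactly
        deficit <- round((targets[ai] - cov()) * npix)
        if (deficit > 0) {
          un <- which(!px[w$rows, w$cols])
          take <- sample(un, min(deficit, length(un)))
          sub <- px[w$rows, w$cols]
          sub[take] <- TRUE
          px[w$rows, w$cols] <- sub
        }
      }
      px
    })
    for (ai in seq_along(areas)) {
      achieved[ai] <- pixel_coverage(img, layout[layout$area == areas[ai], ])
    }
    gt <- tibble(area = areas, target = targets, achieved = achieved)
  }
  attr(img, "ground_truth") <- gt
  img
}

#' @export
autoplot.stain_image <- function(object, ...) {
  df <- expand.grid(
    y = (seq_len(nrow(object$pixels)) - 0.5) * object$resolution +
      object$origin[2],
    x = (seq_len(ncol(object$pixels)) - 0.5) * object$resolution +
      object$origin[1]
  )
  df$stained <- as.vector(object$pixels)
  ggplot(df, aes(.data$x * 1e3, .data$y * 1e3, fill = .data$stained)) +
    geom_raster() +
    scale_fill_manual(values = c(`FALSE` = "grey95", `TRUE` = "steelblue4")) +
    coord_equal() +
    labs(x = "x (mm)", y = "y (mm)", fill = "stained",
         title = "Synthetic water-sensitive paper")
}

#' Write a stain image as an ASCII portable bitmap (PBM, P1)
#'
#' @param img A [stain_image()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stain_pbm <- function(img, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("P1", con)
  writeLines(sprintf("# resolution_mm_per_px %.9g", img$resolution * 1e3), con)
  writeLines(sprintf("%d %d", ncol(img$pixels), nrow(img$pixels)), con)
  apply(img$pixels, 1, function(row) {
    writeLines(paste(as.integer(row), collapse = " "), con)
  })
  invisible(path)
}

#' Read an ASCII portable bitmap (PBM, P1) stain image
#'
#' @param path File path.
#' @param layout Area layout to attach; `NULL` derives a single full-frame
#'   rectangle.
#' @param resolution Pixel size (m/pixel); `NULL` reads the resolution
#'   comment written by [write_stain_pbm()] (falling back to 0.25 mm).
#' @return A [stain_image()].
#' @export
read_stain_pbm <- function(path, layout = NULL, resolution = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2 || trimws(lines[1]) != "P1") {
    stop_domain("not an ASCII PBM (P1) file")
  }
  res_line <- grep("^# resolution_mm_per_px", lines, value = TRUE)
  if (is.null(resolution)) {
    resolution <- if (length(res_line) > 0) {
      as.numeric(sub("^# resolution_mm_per_px\\s+", "", res_line[1])) * 1e-3
    } else 2.5e-4
  }
  body <- lines[-1]
  body <- body[!grepl("^#", body)]
  tokens <- as.integer(unlist(strsplit(paste(body, collapse = " "), "\\s+")))
  tokens <- tokens[!is.na(tokens)]
  nx <- tokens[1]; ny <- tokens[2]
  bits <- tokens[-(1:2)]
  if (length(bits) != nx * ny) stop_domain("PBM pixel count mismatch")
  pixels <- matrix(as.logical(bits), ny, nx, byrow = TRUE)
  if (is.null(layout)) {
    layout <- tibble(area = "frame", xmin = 0, xmax = nx * resolution,
                     ymin = 0, ymax = ny * resolution)
  }
  stain_image(pixels, resolution, layout)
}

#' Ground deposition map of a simulation run
#'
#' Bins the masses of droplets that reached the ground onto a regular grid
#' over the domain cross-section.
#'
#' @param sim A `spray_sim` from [run_simulation()].
#' @param nx,ny Grid size.
#' @return A matrix (kg per cell) with attributes `xlim`, `ylim` (m).
#' @export
deposition_map <- function(sim, nx = 40, ny = 40) {
  half <- sim$config$domain / 2
  m <- matrix(0, ny, nx)
  h <- sim$ground_hits
  if (nrow(h) > 0) {
    ci <- pmin(pmax(ceiling((h$x + half[1]) / (2 * half[1]) * nx), 1), nx)
    ri <- pmin(pmax(ceiling((h$y + half[2]) / (2 * half[2]) * ny), 1), ny)
    for (k in seq_along(ci)) m[ri[k], ci[k]] <- m[ri[k], ci[k]] + h$mass[k]
  }
  attr(m, "xlim") <- c(-half[1], half[1])
  attr(m, "ylim") <- c(-half[2], half[2])
  m
}

#' Write a matrix as an ASCII portable graymap (PGM, P2)
#'
#' Values are scaled linearly to 0-255 (maximum value maps to 255).
#'
#' @param m Numeric matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  mx <- max(m, 1e-300)
  g <- round(m / mx * 255)
  writeLines("P2", con)
  writeLines(sprintf("%d %d", ncol(m), nrow(m)), con)
  writeLines("255", con)
  apply(g, 1, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}
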