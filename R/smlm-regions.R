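# 8-connected component labeling of a binary matrix (iterative flood fill)
.label_components8 <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  current <- 0L
  fg <- which(mask > 0)
  for (start in fg) {
    if (labels[start] != 0L) next
    current <- current + 1L
    stack <- start
    labels[start] <- current
    while (length(stack) > 0) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((p - 1L) %% nr) + 1L
      c <- ((p - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr
        cc <- c + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
          q <- (cc - 1L) * nr + rr
          if (mask[q] > 0 && labels[q] == 0L) {
            labels[q] <- current
            stack <- c(stack, q)
          }
        }
      }
    }
  }
  list(labels = labels, n = current)
}

# render one channel to a binary mask: 2D histogram, Gaussian blur, Otsu,
# dilation
.render_channel_mask <- function(x_nm, y_nm, origin, dim_px, render_px,
                                 smooth_sigma, dilation_px) {
  col <- floor((x_nm - origin[1]) / render_px) + 1L
  row <- floor((y_nm - origin[2]) / render_px) + 1L
  ok <- row >= 1 & row <= dim_px[1] & col >= 1 & col <= dim_px[2]
  img <- matrix(0, dim_px[1], dim_px[2])
  if (any(ok)) {
    counts <- table(factor(row[ok], levels = seq_len(dim_px[1])),
                    factor(col[ok], levels = seq_len(dim_px[2])))
    img <- matrix(as.numeric(counts), dim_px[1], dim_px[2])
  }
  if (max(img) == 0) return(matrix(FALSE, dim_px[1], dim_px[2]))
  sm <- EBImage::gblur(img, sigma = smooth_sigma)
  sm_norm <- sm / max(sm)
  thr <- EBImage::otsu(EBImage::Image(sm_norm))
  bin <- sm_norm > thr
  if (dilation_px > 0) {
    brush <- EBImage::makeBrush(2 * dilation_px + 1, shape = "disc")
    bin <- EBImage::dilate(EBImage::Image(bin * 1), brush) > 0
  }
  matrix(as.logical(bin), dim_px[1], dim_px[2])
}

#' Build synapse region masks from the two localization channels
#'
#' Each channel is rendered to a low-resolution image (2D histogram at
#' `render_px` nanometre pixels), Gaussian-smoothed (sd 1 px), thresholded
#' by Otsu's method, and dilated; the synapse regions are the 8-connected
#' components of the intersection of the two binary masks — mimicking how
#' synapses are identified from overlaid pre- and postsynaptic marker
#' images. A user-supplied binary mask (matrix, same convention: rows =
#' y, columns = x, at `render_px`) bypasses rendering entirely.
#'
#' @param rim_locs,glua_locs Localization tibbles (`x_nm`, `y_nm`).
#' @param render_px Render pixel size in nm (default 100).
#' @param smooth_sigma Gaussian smoothing sd in pixels (default 1).
#' @param dilation_px Binary dilation radius in pixels (default 2).
#' @param mask Optional user-supplied binary matrix used as-is.
#' @param origin Coordinate (x, y) in nm of the raster's top-left corner
#'   (default `c(0, 0)`).
#' @return Object of class `synapse_regions`: list with `labels` (integer
#'   matrix, 0 = outside), `n_regions`, `render_px`, `origin`,
#'   `provenance` (`rendered` or `user`). An empty intersection yields
#'   zero regions with a warning.
#' @export
build_synapse_regions <- function(rim_locs, glua_locs, render_px = 100,
                                  smooth_sigma = 1, dilation_px = 2,
                                  mask = NULL, origin = c(0, 0)) {
  if (!is.null(mask)) {
    lab <- .label_components8(mask > 0)
    return(structure(
      list(labels = lab$labels, n_regions = lab$n, render_px = render_px,
           origin = origin, provenance = "user"),
      class = "synapse_regions"
    ))
  }
  check_columns(rim_locs, c("x_nm", "y_nm"), "RIM localizations")
  check_columns(glua_locs, c("x_nm", "y_nm"), "GluA localizations")
  if (nrow(rim_locs) == 0 || nrow(glua_locs) == 0) {
    abort("both channels must be non-empty (or supply a user mask)")
  }
  max_x <- max(rim_locs$x_nm, glua_locs$x_nm)
  max_y <- max(rim_locs$y_nm, glua_locs$y_nm)
  dim_px <- c(ceiling((max_y - origin[2]) / render_px) + 1L,
              ceiling((max_x - origin[1]) / render_px) + 1L)
  m_rim <- .render_channel_mask(rim_locs$x_nm, rim_locs$y_nm, origin, dim_px,
                                render_px, smooth_sigma, dilation_px)
  m_glua <- .render_channel_mask(glua_locs$x_nm, glua_locs$y_nm, origin, dim_px,
                                 render_px, smooth_sigma, dilation_px)
  inter <- m_rim & m_glua
  if (!any(inter)) warn("channel masks do not intersect: empty synapse region set")
  lab <- .label_components8(inter)
  structure(
    list(labels = lab$labels, n_regions = lab$n, render_px = render_px,
         origin = origin, provenance = "rendered"),
    class = "synapse_regions"
  )
}

#' @export
print.synapse_regions <- function(x, ...) {
  cat(sprintf("<synapse_regions> %d region(s), %g nm/px, %s\n",
              x$n_regions, x$render_px, x$provenance))
  invisible(x)
}

# region id containing each (x, y) nm coordinate; 0 if none
region_at <- function(regions, x_nm, y_nm) {
  col <- floor((x_nm - regions$origin[1]) / regions$render_px) + 1L
  row <- floor((y_nm - regions$origin[2]) / regions$render_px) + 1L
  out <- integer(length(x_nm))
  ok <- row >= 1 & row <= nrow(regions$labels) &
    col >= 1 & col <= ncol(regions$labels)
  out[ok] <- regions$labels[cbind(row[ok], col[ok])]
  out
}

#' Assign SSDs to synapse regions and count them per synapse
#'
#' An SSD belongs to the region containing its centroid; SSDs whose
#' centroid falls outside every region are reported as unassigned
#' (`synapse_id = NA`).
#'
#' @param ssds An [ssd_metrics()] table (possibly several channels bound
#'   together).
#' @param regions A [build_synapse_regions()] result.
#' @return List: `ssds` (input with a `synapse_id` column) and `counts`
#'   (tibble `synapse_id`, `channel`, `n_ssd`, covering every region and
#'   channel including zero counts).
#' @export
assign_and_count <- function(ssds, regions) {
  stopifnot(inherits(regions, "synapse_regions"))
  check_columns(ssds, c("x_nm", "y_nm", "channel"), "SSD table")
  rid <- region_at(regions, ssds$x_nm, ssds$y_nm)
  ssds$synapse_id <- ifelse(rid == 0, NA_integer_, rid)
  channels <- unique(ssds$channel)
  counts <- tidyr::expand_grid(
    synapse_id = seq_len(regions$n_regions),
    channel = channels
  )
  tallied <- ssds %>%
    filter(!is.na(.data$synapse_id)) %>%
    dplyr::count(.data$synapse_id, .data$channel, name = "n_ssd")
  counts <- counts %>%
    left_join(tallied, by = c("synapse_id", "channel")) %>%
    mutate(n_ssd = ifelse(is.na(.data$n_ssd), 0L, .data$n_ssd))
  list(ssds = ssds, counts = counts)
}

#' Pair receptor SSDs with their nearest scaffold SSD (nanocolumns)
#'
#' For each postsynaptic (GluA) SSD, finds the nearest presynaptic (RIM)
#' SSD centroid by Euclidean distance; the pair is kept when that distance
#' is within `search_radius` (default 350 nm), otherwise the receptor SSD
#' is reported unpaired. Pairing depends on centroids only.
#'
#' @param glua_ssds,rim_ssds SSD tables ([ssd_metrics()]).
#' @param search_radius Pairing radius in nm.
#' @return Tibble of class `nanocolumn_pairing`: `glua_ssd_id`,
#'   `rim_ssd_id` (`NA` when unpaired), `distance_nm` (nearest-neighbor
#'   distance, also reported for unpaired SSDs), `paired`.
#' @export
pair_nanocolumns <- function(glua_ssds, rim_ssds, search_radius = 350) {
  check_columns(glua_ssds, c("ssd_id", "x_nm", "y_nm"), "GluA SSDs")
  if (nrow(rim_ssds) == 0) {
    out <- tibble(glua_ssd_id = glua_ssds$ssd_id, rim_ssd_id = NA_integer_,
                  distance_nm = NA_real_, paired = FALSE)
  } else {
    rows <- purrr::map(seq_len(nrow(glua_ssds)), function(i) {
      d <- sqrt((rim_ssds$x_nm - glua_ssds$x_nm[i])^2 +
                  (rim_ssds$y_nm - glua_ssds$y_nm[i])^2)
      j <- which.min(d)
      tibble(
        glua_ssd_id = glua_ssds$ssd_id[i],
        rim_ssd_id = if (d[j] <= search_radius) rim_ssds$ssd_id[j] else NA_integer_,
        distance_nm = d[j],
        paired = d[j] <= search_radius
      )
    })
    out <- bind_rows(rows)
  }
  attr(out, "search_radius") <- search_radius
  class(out) <- c("nanocolumn_pairing", class(out))
  out
}

#' Relative-frequency histogram of nanocolumn centroid distances
#'
#' @param pairing A [pair_nanocolumns()] result.
#' @param bin_width Bin width in nm (default 20).
#' @param paired_only Use only paired SSDs (default TRUE; the pairing
#'   radius caps the distances entering the published distribution).
#' @return Tibble `bin_mid`, `count`, `rel_freq`.
#' @export
pairing_histogram <- function(pairing, bin_width = 20, paired_only = TRUE) {
  d <- if (paired_only) pairing$distance_nm[pairing$paired] else pairing$distance_nm
  d <- d[is.finite(d)]
  if (length(d) == 0) {
    return(tibble(bin_mid = double(), count = integer(), rel_freq = double()))
  }
  breaks <- seq(0, (max(d) %/% bin_width + 1) * bin_width, by = bin_width)
  h <- hist(d, breaks = breaks, plot = FALSE)
  tibble(bin_mid = h$mids, count = h$counts, rel_freq = h$counts / sum(h$counts))
}

#' Summary statistics of a nanocolumn pairing
#'
#' Mean centroid-to-centroid distance over paired SSDs (the capped
#' statistic), the mean over all receptor SSDs regardless of the cap, and
#' the paired fraction.
#'
#' @param pairing A [pair_nanocolumns()] result.
#' @return One-row tibble.
#' @export
pairing_summary <- function(pairing) {
  tibble(
    n_glua = nrow(pairing),
    n_paired = sum(pairing$paired),
    mean_distance_paired_nm = mean(pairing$distance_nm[pairing$paired]),
    mean_distance_all_nm = mean(pairing$distance_nm, na.rm = TRUE),
    frac_paired = mean(pairing$paired)
  )
}
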