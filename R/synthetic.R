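#' Synthetic ISH study generation
#'
#' Brightfield in situ hybridization (ISH) images show dark (digoxigenin)
#' stain on a light tissue section over a near-white scanner background.
#' The generator emulates the qualitative vocabulary used by expert
#' annotators of cortical ISH data: an expression intensity grade from 0
#' (no signal) to 5 (over-labelling), and a spatial pattern class
#' (widespread, scattered, laminar, sparse, none). Each gene receives a
#' fixed phenotype; each donor contributes a staining gain and a tissue
#' shape, so that images of the same gene vary across donors the way real
#' sections do.
#'
#' @name synthetic_ish
NULL

PATTERN_CLASSES <- c("widespread", "scattered", "laminar", "sparse", "none")

#' Sample gene phenotypes
#'
#' Draws one phenotype per gene such that distinct genes are visually
#' separable in expectation: (pattern_class, intensity_grade) combinations
#' are dealt from a shuffled grid without immediate repetition, and cell
#' density / cell radius are drawn per gene. Cell density is the expected
#' number of stained cells per 1000 px^2 of tissue.
#'
#' @param n_genes number of genes (>= 2).
#' @param seed integer seed.
#' @return a data.frame with one row per gene: \code{gene_id},
#'   \code{intensity_grade} (0..5), \code{pattern_class},
#'   \code{cell_density}, \code{cell_radius_px}, and the 6-band laminar
#'   profile \code{lam1..lam6} (rows sum to 1; only consulted for laminar
#'   genes).
#' @export
sample_phenotypes <- function(n_genes, seed) {
  if (n_genes < 2) stop_invalid("n_genes must be >= 2, got %s", n_genes)
  with_seed(seed, {
    # grid of separable (pattern, grade) combinations; grade 0 only with "none"
    grid <- rbind(
      expand.grid(pattern = c("widespread", "scattered", "laminar", "sparse"),
                  grade = 1:5, stringsAsFactors = FALSE),
      data.frame(pattern = "none", grade = 0L)
    )
    grid <- grid[sample.int(nrow(grid)), ]
    idx <- ((seq_len(n_genes) - 1L) %% nrow(grid)) + 1L
    pattern <- grid$pattern[idx]
    grade <- as.integer(grid$grade[idx])

    dens_base <- c(widespread = 10, scattered = 3, laminar = 8,
                   sparse = 0.6, none = 0)
    density <- dens_base[pattern] * exp(stats::runif(n_genes, -0.6, 0.6))
    radius <- sample(2:4, n_genes, replace = TRUE)

    lam <- matrix(0, n_genes, 6)
    for (i in seq_len(n_genes)) {
      w <- stats::rexp(6) * 0.15
      if (pattern[i] == "laminar") {
        main <- sample(2:5, 1L)           # an interior "layer"
        w[main] <- w[main] + 6
        if (stats::runif(1) < 0.5) {
          nb <- main + sample(c(-1L, 1L), 1L)
          w[nb] <- w[nb] + 2
        }
      } else w <- w + 1
      lam[i, ] <- w / sum(w)
    }
    ph <- data.frame(
      gene_id = sprintf("G%04d", seq_len(n_genes)),
      intensity_grade = grade,
      pattern_class = pattern,
      cell_density = unname(density),
      cell_radius_px = radius,
      stringsAsFactors = FALSE
    )
    colnames(lam) <- paste0("lam", 1:6)
    cbind(ph, lam)
  })
}

laminar_profile_of <- function(phenotype) {
  p <- as.numeric(phenotype[paste0("lam", 1:6)])
  if (any(!is.finite(p)) || any(p < 0)) stop_invalid("invalid laminar profile")
  p / sum(p)
}

#' Sample donor profiles
#'
#' @param n_donors number of donors.
#' @param seed integer seed.
#' @param prop_schizophrenia fraction of donors labelled schizophrenia
#'   (assigned deterministically by alternation after shuffling).
#' @return data.frame with donor_id, stain_gain, tissue_shape_seed,
#'   diagnosis, age, sex, ph, pmi_hours, smoker, ancestry.
#' @export
sample_donors <- function(n_donors, seed, prop_schizophrenia = 0.5) {
  with_seed(seed, {
    n_scz <- round(n_donors * prop_schizophrenia)
    diag <- sample(c(rep("schizophrenia", n_scz),
                     rep("control", n_donors - n_scz)))
    data.frame(
      donor_id = sprintf("D%03d", seq_len(n_donors)),
      stain_gain = pmin(3.5, pmax(0.35, exp(stats::rnorm(n_donors, 0, 0.5)))),
      tissue_shape_seed = sample.int(1e6, n_donors),
      diagnosis = diag,
      age = round(stats::runif(n_donors, 22, 56)),
      sex = sample(c("M", "F"), n_donors, replace = TRUE),
      ph = round(stats::rnorm(n_donors, 6.7, 0.25), 2),
      pmi_hours = round(stats::runif(n_donors, 10, 68), 1),
      smoker = sample(c("yes", "no", "unknown"), n_donors, replace = TRUE,
                      prob = c(0.4, 0.5, 0.1)),
      ancestry = sample(c("european", "african", "asian"), n_donors,
                        replace = TRUE, prob = c(0.6, 0.25, 0.15)),
      stringsAsFactors = FALSE
    )
  })
}

# Star-shaped tissue blob: an ellipse whose radius is perturbed by a
# low-order Fourier series; star-shapedness guarantees a single connected
# component. Returns a logical matrix (rows = y, cols = x).
tissue_blob_mask <- function(side_px, shape_seed) {
  with_seed(shape_seed, {
    cx <- side_px * stats::runif(1, 0.45, 0.55)
    cy <- side_px * stats::runif(1, 0.45, 0.55)
    rx <- side_px * stats::runif(1, 0.3, 0.42)
    ry <- side_px * stats::runif(1, 0.3, 0.42)
    k <- 2:5
    amp <- stats::runif(4, 0, 0.22) / (k / 2)
    phase <- stats::runif(4, 0, 2 * pi)
    target <- stats::runif(1, 0.38, 0.65)

    mask_for <- function(rx, ry) {
      ys <- matrix(seq_len(side_px) - cy, side_px, side_px)
      xs <- matrix(seq_len(side_px) - cx, side_px, side_px, byrow = TRUE)
      theta <- atan2(ys / ry, xs / rx)
      rho <- sqrt((xs / rx)^2 + (ys / ry)^2)
      bound <- 1 + amp[1] * cos(k[1] * theta + phase[1]) +
        amp[2] * cos(k[2] * theta + phase[2]) +
        amp[3] * cos(k[3] * theta + phase[3]) +
        amp[4] * cos(k[4] * theta + phase[4])
      rho <= bound
    }
    m <- mask_for(rx, ry)
    # one corrective rescale toward the target area fraction
    f <- mean(m)
    s <- sqrt(target / max(f, 1e-6))
    rx <- min(rx * s, side_px * 0.48)
    ry <- min(ry * s, side_px * 0.48)
    mask_for(rx, ry)
  })
}

# 6 depth bands from distance-to-boundary quantiles within the tissue;
# band 1 is the outermost "layer", band 6 the deepest.
depth_bands <- function(mask) {
  dm <- EBImage::distmap(matrix(as.numeric(mask), nrow(mask)))
  d <- dm[mask]
  qs <- stats::quantile(d, probs = seq(0, 1, length.out = 7), names = FALSE)
  qs <- cummax(qs + seq(0, 6) * 1e-9)      # strictly increasing for cut()
  band <- matrix(NA_integer_, nrow(mask), ncol(mask))
  band[mask] <- as.integer(cut(d, breaks = qs, include.lowest = TRUE))
  band
}

#' Render one synthetic ISH image
#'
#' Background pixels are near white (>= 0.97 of full scale with slight
#' Gaussian noise); the tissue section is a single connected irregular
#' blob of lighter gray; stained cells are dark Gaussian blobs whose
#' spatial density follows the gene's pattern class and whose darkness
#' scales with intensity_grade x the donor's stain_gain.
#'
#' @param phenotype one row of a phenotype table (see
#'   \code{\link{sample_phenotypes}}), or a list with the same fields.
#' @param donor one row of a donor table (needs \code{stain_gain} and
#'   \code{tissue_shape_seed}).
#' @param side_px image side in pixels (>= 64).
#' @param seed integer seed for cell placement and pixel noise.
#' @return a list with \code{image} (side x side matrix in [0,1]),
#'   \code{mask} (logical tissue support), and \code{cells}
#'   (data.frame of rendered cell centres: x, y, band).
#' @export
render_image <- function(phenotype, donor, side_px, seed) {
  if (side_px < 64) stop_invalid("side_px must be >= 64, got %s", side_px)
  phenotype <- as.list(phenotype)
  donor <- as.list(donor)
  grade <- as.integer(phenotype$intensity_grade)
  pattern <- as.character(phenotype$pattern_class)
  if (!pattern %in% PATTERN_CLASSES)
    stop_invalid("unknown pattern_class '%s'", pattern)
  gain <- as.numeric(donor$stain_gain)
  if (!is.finite(gain) || gain <= 0.25 || gain >= 4)
    stop_invalid("stain_gain must lie in (0.25, 4)")

  mask <- tissue_blob_mask(side_px, substream_seed(seed, "tissue",
                                                   donor$tissue_shape_seed))
  with_seed(substream_seed(seed, "render"), {
    img <- matrix(pmax(0.97, pmin(1, stats::rnorm(side_px^2, 0.99, 0.006))),
                  side_px, side_px)
    # per-section nuisance: tissue tint (thickness) and staining-batch
    # strength vary image to image, as on real scanned slides
    tissue_base <- stats::rnorm(1, 0.88, 0.015)
    stain_mult <- exp(stats::rnorm(1, 0, 0.15))
    img[mask] <- pmin(0.955, pmax(0.75, stats::rnorm(sum(mask), tissue_base,
                                                     0.02)))

    cells <- data.frame(x = integer(0), y = integer(0), band = integer(0))
    if (grade > 0 && pattern != "none") {
      band <- depth_bands(mask)
      area <- sum(mask)
      # stronger expression shows more detectably stained cells as well as
      # darker ones; the base density applies at grade 3
      n_cells <- stats::rpois(1, phenotype$cell_density *
                                (0.4 + 0.2 * grade) * area / 1000)
      if (n_cells > 0) {
        tissue_idx <- which(mask)
        if (pattern == "laminar") {
          prof <- laminar_profile_of(phenotype)
          bands_drawn <- sample.int(6, n_cells, replace = TRUE, prob = prof)
          idx <- integer(n_cells)
          for (b in unique(bands_drawn)) {
            pool <- which(band == b)
            if (length(pool) == 0L) pool <- tissue_idx
            sel <- bands_drawn == b
            idx[sel] <- pool[sample.int(length(pool), sum(sel), replace = TRUE)]
          }
        } else {
          idx <- tissue_idx[sample.int(length(tissue_idx), n_cells,
                                       replace = TRUE)]
        }
        cy <- ((idx - 1L) %% side_px) + 1L
        cx <- ((idx - 1L) %/% side_px) + 1L
        cells <- data.frame(x = cx, y = cy, band = band[idx])

        r <- max(1L, as.integer(phenotype$cell_radius_px))
        amp <- min(0.85, 0.14 * grade * gain * stain_mult)
        w <- 2L * r + 1L
        off <- seq(-r, r)
        kern <- amp * exp(-(outer(off^2, off^2, "+")) / (2 * (r / 1.4)^2))
        for (i in seq_len(n_cells)) {
          ys <- (cy[i] - r):(cy[i] + r)
          xs <- (cx[i] - r):(cx[i] + r)
          ky <- which(ys >= 1 & ys <= side_px)
          kx <- which(xs >= 1 & xs <= side_px)
          img[ys[ky], xs[kx]] <- img[ys[ky], xs[kx]] - kern[ky, kx]
        }
        img <- pmax(img, 0.03)
      }
    }
    # histology artifacts: tissue folds (dark streaks) and bubbles (dark
    # rings), confined to the section so the background stays clean
    n_streak <- stats::rpois(1, 1.5)
    for (s in seq_len(n_streak)) {
      ti <- which(mask)
      a <- ti[sample.int(length(ti), 1L)]
      b <- ti[sample.int(length(ti), 1L)]
      ay <- ((a - 1L) %% side_px) + 1L; ax <- ((a - 1L) %/% side_px) + 1L
      by <- ((b - 1L) %% side_px) + 1L; bx <- ((b - 1L) %/% side_px) + 1L
      npt <- max(abs(bx - ax), abs(by - ay)) + 1L
      xs <- round(seq(ax, bx, length.out = npt))
      ys <- round(seq(ay, by, length.out = npt))
      dark <- stats::runif(1, 0.1, 0.45)
      w <- sample(0:1, 1L)
      for (dx in -w:w) for (dy in -w:w) {
        xi <- pmin(pmax(xs + dx, 1L), side_px)
        yi <- pmin(pmax(ys + dy, 1L), side_px)
        ii <- (xi - 1L) * side_px + yi
        keep <- mask[ii]
        img[ii[keep]] <- pmax(img[ii[keep]] - dark, 0.03)
      }
    }
    n_ring <- stats::rpois(1, 1)
    for (s in seq_len(n_ring)) {
      ti <- which(mask)
      cidx <- ti[sample.int(length(ti), 1L)]
      ccy <- ((cidx - 1L) %% side_px) + 1L; ccx <- ((cidx - 1L) %/% side_px) + 1L
      rr <- stats::runif(1, 5, 15)
      dark <- stats::runif(1, 0.1, 0.4)
      th <- seq(0, 2 * pi, length.out = ceiling(2 * pi * rr * 2))
      xi <- pmin(pmax(round(ccx + rr * cos(th)), 1L), side_px)
      yi <- pmin(pmax(round(ccy + rr * sin(th)), 1L), side_px)
      ii <- unique((xi - 1L) * side_px + yi)
      keep <- mask[ii]
      img[ii[keep]] <- pmax(img[ii[keep]] - dark, 0.03)
    }
    # per-section optics: slight defocus and sensor noise vary image to
    # image on real slide scanners
    blur_sigma <- stats::runif(1, 0, 1.2)
    if (blur_sigma > 0.25)
      img <- as.matrix(EBImage::gblur(EBImage::Image(img),
                                      sigma = blur_sigma))
    img <- img + stats::rnorm(length(img), 0, 0.008)
    img <- pmin(pmax(img, 0), 1)
    list(image = img, mask = mask, cells = cells)
  })
}

#' Specify a synthetic study design
#'
#' @param n_genes number of genes (>= 2).
#' @param n_donors number of donors.
#' @param genes_per_donor genes assayed per donor (integer or \code{"all"}).
#' @param images_per_gene_donor images per (gene, donor) pair.
#' @param image_side_px side of each generated image.
#' @param diagnosis_effect_genes character vector of gene ids whose
#'   rendering intensity is shifted in schizophrenia donors.
#' @param diagnosis_effect_size intensity-grade shift (rounded).
#' @param master_seed master seed; all stage seeds derive from it.
#' @return a validated list of class \code{"study_spec"}.
#' @export
study_spec <- function(n_genes, n_donors, genes_per_donor = "all",
                       images_per_gene_donor = 1L, image_side_px = 128L,
                       diagnosis_effect_genes = character(0),
                       diagnosis_effect_size = 0,
                       master_seed = 1L) {
  if (n_genes < 2) stop_invalid("n_genes must be >= 2")
  if (n_donors < 1) stop_invalid("n_donors must be >= 1")
  if (!identical(genes_per_donor, "all")) {
    genes_per_donor <- as.integer(genes_per_donor)
    if (genes_per_donor > n_genes)
      stop_invalid("genes_per_donor exceeds n_genes")
  }
  if (image_side_px < 64) stop_invalid("image_side_px must be >= 64")
  structure(list(
    n_genes = as.integer(n_genes), n_donors = as.integer(n_donors),
    genes_per_donor = genes_per_donor,
    images_per_gene_donor = as.integer(images_per_gene_donor),
    image_side_px = as.integer(image_side_px),
    diagnosis_effect_genes = as.character(diagnosis_effect_genes),
    diagnosis_effect_size = diagnosis_effect_size,
    master_seed = as.integer(master_seed)
  ), class = "study_spec")
}

#' Generate a complete synthetic ISH study
#'
#' Genes are dealt to donors without replacement within each donor,
#' preferring the least-assayed genes so gene coverage stays balanced
#' (mimicking study designs where each gene is assayed in a few brains).
#' For genes carrying a planted diagnosis effect, images from
#' schizophrenia donors are rendered with the intensity grade shifted by
#' \code{round(diagnosis_effect_size)} (clamped to 0..5); the recorded
#' truth phenotypes keep the unshifted grade.
#'
#' @param spec a \code{\link{study_spec}}.
#' @return a list of class \code{"ish_study"}: \code{images} (named list
#'   of matrices), \code{image_table}, \code{donor_table},
#'   \code{annotation_table}, \code{truth_masks}, \code{truth_phenotypes},
#'   \code{spec}.
#' @export
generate_study <- function(spec) {
  stopifnot(inherits(spec, "study_spec"))
  ms <- spec$master_seed
  phen <- sample_phenotypes(spec$n_genes, substream_seed(ms, "phenotypes"))
  donors <- sample_donors(spec$n_donors, substream_seed(ms, "donors"))

  gpd <- if (identical(spec$genes_per_donor, "all")) spec$n_genes
         else spec$genes_per_donor
  assign_tab <- with_seed(substream_seed(ms, "assign"), {
    usage <- stats::setNames(rep(0L, spec$n_genes), phen$gene_id)
    rows <- vector("list", spec$n_donors)
    for (i in seq_len(spec$n_donors)) {
      key <- stats::runif(spec$n_genes)
      ord <- order(usage, key)                 # least-used genes first
      picked <- phen$gene_id[ord[seq_len(gpd)]]
      usage[picked] <- usage[picked] + 1L
      rows[[i]] <- data.frame(donor_id = donors$donor_id[i],
                              gene_id = picked, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })

  regions <- with_seed(substream_seed(ms, "regions"),
    sample(c("temporal", "visual"),
           nrow(assign_tab) * spec$images_per_gene_donor, replace = TRUE))

  images <- list()
  masks <- list()
  it <- vector("list", nrow(assign_tab) * spec$images_per_gene_donor)
  shift <- as.integer(round(spec$diagnosis_effect_size))
  n <- 0L
  for (r in seq_len(nrow(assign_tab))) {
    g <- assign_tab$gene_id[r]
    d <- assign_tab$donor_id[r]
    ph_row <- phen[phen$gene_id == g, ]
    don_row <- donors[donors$donor_id == d, ]
    if (g %in% spec$diagnosis_effect_genes &&
        don_row$diagnosis == "schizophrenia" && shift != 0L) {
      ph_row$intensity_grade <- max(0L, min(5L, ph_row$intensity_grade + shift))
    }
    for (j in seq_len(spec$images_per_gene_donor)) {
      n <- n + 1L
      image_id <- sprintf("img_%s_%s_%02d", g, d, j)
      rend <- render_image(ph_row, don_row, spec$image_side_px,
                           substream_seed(ms, "render", n))
      images[[image_id]] <- rend$image
      masks[[image_id]] <- rend$mask
      it[[n]] <- data.frame(image_id = image_id, gene_id = g, donor_id = d,
                            region = regions[n], stringsAsFactors = FALSE)
    }
  }
  image_table <- do.call(rbind, it)

  annotation_table <- rbind(
    data.frame(gene_id = phen$gene_id, annotation_name = "intensity_grade",
               value = as.character(phen$intensity_grade),
               stringsAsFactors = FALSE),
    data.frame(gene_id = phen$gene_id, annotation_name = "pattern_class",
               value = phen$pattern_class, stringsAsFactors = FALSE)
  )

  structure(list(images = images, image_table = image_table,
                 donor_table = donors, annotation_table = annotation_table,
                 truth_masks = masks, truth_phenotypes = phen, spec = spec),
            class = "ish_study")
}

#' @export
print.ish_study <- function(x, ...) {
  cat(sprintf("<ish_study> %d genes, %d donors, %d images (%dpx)\n",
              x$spec$n_genes, x$spec$n_donors, length(x$images),
              x$spec$image_side_px))
  invisible(x)
}
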