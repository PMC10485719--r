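#' Synthetic dermoscopic image collections
#'
#' The generator emulates the on-disk shape of the HAM10000 collection — RGB
#' lesion photographs plus a metadata table with `image_id`, `lesion_id` and a
#' seven-class diagnosis `dx` — at desk scale, and additionally records a
#' ground-truth binary lesion mask per image so that saliency localisation can
#' be scored. Each class is rendered as a distinct phenotype on a skin-like
#' background, parameterised by base colour, shape eccentricity, border
#' irregularity and internal texture frequency. The phenotypes are separable
#' by a small CNN yet overlap enough (three brownish classes) that classifier
#' and retrieval errors occur.
#'
#' @name synthetic-data
NULL

# per-class phenotype: base RGB, eccentricity, border modulation amplitude,
# internal texture frequency (cycles per image)
lesion_phenotypes <- function() {
  data.frame(
    dx      = lesion_classes(),
    r       = c(0.80, 0.78, 0.62, 0.45, 0.25, 0.52, 0.75),
    g       = c(0.55, 0.62, 0.45, 0.33, 0.15, 0.34, 0.25),
    b       = c(0.48, 0.62, 0.30, 0.28, 0.12, 0.22, 0.35),
    ecc     = c(0.50, 0.30, 0.40, 0.15, 0.65, 0.20, 0.30),
    border  = c(0.22, 0.12, 0.16, 0.06, 0.28, 0.08, 0.10),
    texfreq = c(9, 3, 6, 2, 7, 4, 2),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic dataset
#'
#' @param n_images Number of images to generate (>= 0).
#' @param class_proportions Probability vector over the 7 classes in
#'   [lesion_classes()] order; must sum to 1 (tolerance 1e-9). The default
#'   mirrors the strong class imbalance of dermoscopy archives (about 67%
#'   nevi, 11% melanoma).
#' @param follow_up_rate Fraction in \[0,1\] of lesions that contribute a
#'   second, follow-up image (same lesion id and label, re-rendered with a
#'   small spatial jitter and brightness shift).
#' @param image_size Pixels per side of the square images (>= 32).
#' @param seed Integer seed; the whole dataset is a deterministic function of
#'   the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_images = 700,
                           class_proportions = c(0.02, 0.05, 0.11, 0.01,
                                                 0.11, 0.67, 0.03),
                           follow_up_rate = 0.1,
                           image_size = 64,
                           seed = 1L) {
  stopifnot(n_images >= 0, image_size >= 32,
            follow_up_rate >= 0, follow_up_rate <= 1,
            length(class_proportions) == n_lesion_classes(),
            all(class_proportions >= 0))
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1", call. = FALSE)
  structure(list(n_images = as.integer(n_images),
                 class_proportions = class_proportions,
                 follow_up_rate = follow_up_rate,
                 image_size = as.integer(image_size),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate one synthetic lesion image
#'
#' Renders a skin-textured background and a single class-distinctive lesion:
#' an ellipse with class-specific hue, eccentricity, sinusoidally perturbed
#' border and internal texture, softly blended into the background. The
#' returned object carries the exact binary lesion mask.
#'
#' @param label One of [lesion_classes()].
#' @param image_size Pixels per side (>= 32).
#' @param seed Integer seed; output is deterministic in `(label, image_size,
#'   seed)`.
#' @return A `labeled_image`: list with `image_id` (NA until assigned),
#'   `lesion_id`, `pixels` (H x W x 3 array in \[0,1\]), `label`, and
#'   `lesion_mask` (H x W 0/1 matrix).
#' @export
#' @examples
#' img <- generate_image("mel", 64, seed = 2)
#' mean(img$lesion_mask)   # lesion area fraction
generate_image <- function(label, image_size = 64, seed = 1L) {
  assert_class_code(label)
  stopifnot(image_size >= 32)
  ph <- lesion_phenotypes()
  pi_row <- ph[ph$dx == label, ]
  cls_i <- match(label, lesion_classes())
  with_seed_local(derive_seed(seed, 131, cls_i), {
    n <- as.integer(image_size)
    xs <- (seq_len(n) - 0.5) / n
    X <- matrix(xs, n, n, byrow = TRUE)   # column coordinate
    Y <- matrix(xs, n, n)                 # row coordinate

    # skin background: warm base + slow illumination gradient + grain
    base <- c(0.92, 0.80, 0.72)
    gx <- runif(1, -0.05, 0.05); gy <- runif(1, -0.05, 0.05)
    grad <- gx * (X - 0.5) + gy * (Y - 0.5)
    pixels <- array(0, dim = c(n, n, 3))
    for (ch in 1:3)
      pixels[, , ch] <- base[ch] + grad +
        matrix(rnorm(n * n, 0, 0.02), n, n)

    # lesion geometry
    cx <- runif(1, 0.42, 0.58); cy <- runif(1, 0.42, 0.58)
    theta <- runif(1, 0, pi)
    af <- runif(1, 0.08, 0.26)                # nominal area fraction
    ecc <- pi_row$ecc
    a <- sqrt(af / (pi * sqrt(1 - ecc^2)))
    b <- a * sqrt(1 - ecc^2)
    U <- ((X - cx) * cos(theta) + (Y - cy) * sin(theta)) / a
    V <- (-(X - cx) * sin(theta) + (Y - cy) * cos(theta)) / b
    rho <- sqrt(U^2 + V^2)
    phi <- atan2(V, U)
    amp <- pi_row$border
    w <- abs(rnorm(3)); w <- w / sqrt(sum(w^2))
    pha <- runif(3, 0, 2 * pi)
    modl <- amp * (w[1] * sin(3 * phi + pha[1]) +
                   w[2] * sin(5 * phi + pha[2]) +
                   w[3] * sin(7 * phi + pha[3]))
    boundary <- 1 + modl
    mask <- (rho <= boundary) * 1

    # lesion appearance: class hue + oriented sinusoidal texture + grain
    tau <- runif(1, 0, pi)
    tex <- sin(2 * pi * pi_row$texfreq * (X * cos(tau) + Y * sin(tau)))
    col <- c(pi_row$r, pi_row$g, pi_row$b)
    blend <- pmin(pmax((boundary - rho) / 0.10, 0), 1)  # soft edge
    for (ch in 1:3) {
      les <- col[ch] * (1 + 0.12 * tex) +
        matrix(rnorm(n * n, 0, 0.03), n, n)
      pixels[, , ch] <- blend * les + (1 - blend) * pixels[, , ch]
    }
    pixels[pixels < 0] <- 0
    pixels[pixels > 1] <- 1
    structure(list(image_id = NA_character_, lesion_id = NA_character_,
                   pixels = pixels, label = label, lesion_mask = mask),
              class = "labeled_image")
  })
}

# re-render a follow-up acquisition: integer shift + brightness change
render_followup <- function(img, seed) {
  with_seed_local(seed, {
    n <- dim(img$pixels)[1]
    dx <- sample(-2:2, 1); dy <- sample(-2:2, 1)
    bright <- runif(1, -0.06, 0.06)
    shift2 <- function(M, dy, dx) {
      out <- M
      src_r <- pmin(pmax(seq_len(n) - dy, 1), n)
      src_c <- pmin(pmax(seq_len(n) - dx, 1), n)
      out[] <- M[src_r, src_c]
      out
    }
    px <- img$pixels
    for (ch in 1:3) px[, , ch] <- shift2(px[, , ch], dy, dx) + bright
    px[px < 0] <- 0; px[px > 1] <- 1
    msk <- shift2(img$lesion_mask, dy, dx)
    out <- img
    out$pixels <- px
    out$lesion_mask <- msk
    out
  })
}

#' Generate a synthetic labeled dataset
#'
#' Draws per-class image counts from a seeded multinomial under the spec's
#' class proportions, renders each image, and assigns lesion ids such that a
#' `follow_up_rate` fraction of lesions contribute two images (same lesion id,
#' same label, jittered re-render).
#'
#' @param spec A [synthetic_spec()].
#' @return List with `images` (list of `labeled_image`) and `metadata`
#'   (data.frame with columns `image_id`, `lesion_id`, `dx`).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  classes <- lesion_classes()
  if (spec$n_images == 0L) {
    return(list(images = list(),
                metadata = data.frame(image_id = character(0),
                                      lesion_id = character(0),
                                      dx = character(0),
                                      stringsAsFactors = FALSE)))
  }
  with_seed_local(spec$seed, {
    counts <- as.vector(rmultinom(1, spec$n_images, spec$class_proportions))
    images <- vector("list", spec$n_images)
    meta <- vector("list", spec$n_images)
    img_i <- 0L; les_i <- 0L
    for (ci in seq_along(classes)) {
      m <- counts[ci]
      if (m == 0L) next
      f <- spec$follow_up_rate
      n_lesions <- max(1L, round(m / (1 + f)))
      n_fu <- m - n_lesions
      if (n_fu > n_lesions) {      # follow_up_rate near 1 and odd m
        n_lesions <- ceiling(m / 2); n_fu <- m - n_lesions
      }
      has_fu <- rep(FALSE, n_lesions)
      if (n_fu > 0) has_fu[sample.int(n_lesions, n_fu)] <- TRUE
      for (li in seq_len(n_lesions)) {
        les_i <- les_i + 1L
        lid <- sprintf("LES_%05d", les_i)
        s <- sample.int(2^30, 1)
        base <- generate_image(classes[ci], spec$image_size, seed = s)
        base$lesion_id <- lid
        img_i <- img_i + 1L
        base$image_id <- sprintf("IMG_%05d", img_i)
        images[[img_i]] <- base
        meta[[img_i]] <- c(base$image_id, lid, classes[ci])
        if (has_fu[li]) {
          fu <- render_followup(base, seed = sample.int(2^30, 1))
          fu$lesion_id <- lid
          img_i <- img_i + 1L
          fu$image_id <- sprintf("IMG_%05d", img_i)
          images[[img_i]] <- fu
          meta[[img_i]] <- c(fu$image_id, lid, classes[ci])
        }
      }
    }
    md <- as.data.frame(do.call(rbind, meta), stringsAsFactors = FALSE)
    names(md) <- c("image_id", "lesion_id", "dx")
    list(images = images, metadata = md)
  })
}

#' Write a dataset to disk in the HAM10000 layout
#'
#' 8-bit RGB PNG per image under `dir/images/`, single-channel PNG mask under
#' `dir/masks/`, and `dir/metadata.csv` with header `image_id,lesion_id,dx`.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (img in dataset$images) {
    png::writePNG(img$pixels,
                  file.path(dir, "images", paste0(img$image_id, ".png")))
    png::writePNG(img$lesion_mask,
                  file.path(dir, "masks", paste0(img$image_id, ".png")))
  }
  write.csv(dataset$metadata, file.path(dir, "metadata.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()] (or any HAM10000-layout folder)
#'
#' @param dir Directory containing `images/` and `metadata.csv`; `masks/` is
#'   optional.
#' @return Same structure as [generate_dataset()].
#' @export
read_dataset <- function(dir) {
  md <- read.csv(file.path(dir, "metadata.csv"), stringsAsFactors = FALSE)
  stopifnot(all(c("image_id", "lesion_id", "dx") %in% names(md)))
  has_masks <- dir.exists(file.path(dir, "masks"))
  images <- lapply(seq_len(nrow(md)), function(i) {
    px <- png::readPNG(file.path(dir, "images",
                                 paste0(md$image_id[i], ".png")))
    if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
    if (dim(px)[3] > 3) px <- px[, , 1:3, drop = FALSE]
    msk <- NULL
    mf <- file.path(dir, "masks", paste0(md$image_id[i], ".png"))
    if (has_masks && file.exists(mf)) {
      msk <- png::readPNG(mf)
      if (length(dim(msk)) == 3) msk <- msk[, , 1]
      msk <- (msk > 0.5) * 1
    }
    structure(list(image_id = md$image_id[i], lesion_id = md$lesion_id[i],
                   pixels = px, label = md$dx[i], lesion_mask = msk),
              class = "labeled_image")
  })
  list(images = images, metadata = md[, c("image_id", "lesion_id", "dx")])
}
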