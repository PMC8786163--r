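test_that("phenotype sampling is deterministic, separable, and valid", {
  a <- sample_phenotypes(5, seed = 1)
  b <- sample_phenotypes(5, seed = 1)
  expect_identical(a, b)

  two <- sample_phenotypes(2, seed = 7)
  expect_false(two$pattern_class[1] == two$pattern_class[2] &&
                 two$intensity_grade[1] == two$intensity_grade[2])

  many <- sample_phenotypes(100, seed = 3)
  expect_gte(length(unique(many$intensity_grade)), 4)
  expect_true(all(abs(rowSums(many[paste0("lam", 1:6)]) - 1) < 1e-12))
  # zero grade only for unexpressed genes and vice versa
  expect_true(all((many$intensity_grade == 0) ==
                    (many$pattern_class == "none")))
  expect_error(sample_phenotypes(1, seed = 1), "n_genes")
})

test_that("rendering is deterministic and respects grade and geometry", {
  ph <- sample_phenotypes(4, seed = 2)
  don <- sample_donors(2, seed = 3)

  zero <- ph[1, ]
  zero$intensity_grade <- 0L
  zero$pattern_class <- "none"
  r0 <- render_image(zero, don[1, ], 96, seed = 5)
  expect_equal(nrow(r0$cells), 0L)
  expect_gt(sum(r0$mask), 0)

  expressed <- ph[2, ]
  expressed$intensity_grade <- 4L
  expressed$pattern_class <- "widespread"
  expressed$cell_density <- 8
  r1 <- render_image(expressed, don[1, ], 96, seed = 5)
  r2 <- render_image(expressed, don[1, ], 96, seed = 5)
  expect_identical(r1$image, r2$image)
  expect_gt(nrow(r1$cells), 0)

  # tissue is one connected blob filling 30-80% of the frame
  frac <- mean(r1$mask)
  expect_gt(frac, 0.3)
  expect_lt(frac, 0.8)
  lab <- EBImage::bwlabel(matrix(as.numeric(r1$mask), nrow(r1$mask)))
  expect_equal(max(lab), 1)

  # background well outside the section stays near white
  dist_out <- EBImage::distmap(matrix(as.numeric(!r1$mask), nrow(r1$mask)))
  far_bg <- !r1$mask & dist_out > 4
  expect_gt(min(r1$image[far_bg]), 0.93)

  expect_error(render_image(expressed, don[1, ], 32, seed = 1), "side_px")
})

test_that("laminar patterns place cells in the requested depth band", {
  ph <- sample_phenotypes(2, seed = 9)[1, ]
  ph$pattern_class <- "laminar"
  ph$intensity_grade <- 4L
  ph$cell_density <- 10
  ph[paste0("lam", 1:6)] <- c(0, 1, 0, 0, 0, 0)
  don <- sample_donors(1, seed = 4)
  r <- render_image(ph, don[1, ], 128, seed = 11)
  expect_gt(nrow(r$cells), 10)
  expect_gte(mean(r$cells$band == 2), 0.8)
})

test_that("study generation has consistent tables, counts and determinism", {
  spec <- study_spec(n_genes = 10, n_donors = 4, genes_per_donor = 5,
                     images_per_gene_donor = 1, image_side_px = 96,
                     master_seed = 7)
  st <- generate_study(spec)
  expect_equal(length(st$images), 20L)
  expect_equal(nrow(st$image_table), 20L)
  expect_setequal(st$image_table$image_id, names(st$images))
  expect_true(all(st$image_table$gene_id %in% st$truth_phenotypes$gene_id))
  expect_true(all(st$image_table$donor_id %in% st$donor_table$donor_id))
  # genes unique within donor
  per_donor <- split(st$image_table$gene_id, st$image_table$donor_id)
  expect_true(all(vapply(per_donor, anyDuplicated, integer(1)) == 0))

  st2 <- generate_study(spec)
  expect_identical(st$images, st2$images)
  expect_identical(st$image_table, st2$image_table)

  # annotation table mirrors the truth phenotypes exactly
  ann <- st$annotation_table
  intens <- ann[ann$annotation_name == "intensity_grade", ]
  m <- match(st$truth_phenotypes$gene_id, intens$gene_id)
  expect_identical(as.integer(intens$value[m]),
                   st$truth_phenotypes$intensity_grade)
})

test_that("a planted diagnosis effect darkens schizophrenia images of that gene", {
  ph_base <- sample_phenotypes(2, seed = 21)
  target <- ph_base$gene_id[which(ph_base$intensity_grade > 0)[1]]
  spec <- study_spec(n_genes = 2, n_donors = 8, genes_per_donor = "all",
                     images_per_gene_donor = 1, image_side_px = 96,
                     diagnosis_effect_genes = target,
                     diagnosis_effect_size = 3, master_seed = 21)
  st <- generate_study(spec)
  it <- st$image_table
  diag_of <- stats::setNames(st$donor_table$diagnosis, st$donor_table$donor_id)
  mean_tissue <- function(iid)
    mean(st$images[[iid]][st$truth_masks[[iid]]])
  rows <- it[it$gene_id == target, ]
  scz <- vapply(rows$image_id[diag_of[rows$donor_id] == "schizophrenia"],
                mean_tissue, numeric(1))
  ctl <- vapply(rows$image_id[diag_of[rows$donor_id] == "control"],
                mean_tissue, numeric(1))
  expect_lt(mean(scz), mean(ctl))
})
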