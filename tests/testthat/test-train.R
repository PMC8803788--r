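test_that("body cropping respects the bounding box and the 40% cap", {
  # body filling the grid: no crop
  full <- pet_volume(array(1, c(16, 16, 4)))
  cf <- crop_to_body(full)
  expect_equal(dim(cf$values), c(16L, 16L, 4L))
  # body occupying the central 50%: the cap binds at 40% removal per axis
  v <- array(0, c(40, 40, 4))
  v[11:30, 11:30, ] <- 1
  cc <- crop_to_body(pet_volume(v), crop_fraction_max = 0.4)
  expect_equal(dim(cc$values)[1:2], c(24L, 24L))  # 40 - 16 removed
  # axial extent untouched
  expect_equal(dim(cc$values)[3], 4L)
  # empty mask: warning, no crop
  expect_warning(z <- crop_to_body(pet_volume(array(0, c(16, 16, 4)))),
                 "empty body mask")
  expect_equal(dim(z$values), c(16L, 16L, 4L))
})

test_that("un-cropping inverts cropping with zeros outside", {
  vol <- build_phantom(simple_spec())
  cr <- crop_to_body(vol)
  expect_lt(prod(dim(cr$values)[1:2]), prod(dim(vol$values)[1:2]))
  back <- uncrop_volume(cr)
  expect_equal(dim(back$values), dim(vol$values))
  crop <- attr(cr, "crop")
  inside <- back$values[crop$x[1]:crop$x[2], crop$y[1]:crop$y[2], ]
  expect_identical(inside, cr$values)
  # everything the crop kept is restored in place
  expect_equal(back$values[crop$x[1]:crop$x[2], crop$y[1]:crop$y[2], ],
               vol$values[crop$x[1]:crop$x[2], crop$y[1]:crop$y[2], ])
})

test_that("patch offsets are equally spaced with minimal count", {
  # worked example: extent 100, patch 40 -> offsets {0, 30, 60}
  expect_identical(petdle:::axis_offsets(100L, 40L), c(0L, 30L, 60L))
  # extent equal to patch: single patch
  expect_identical(petdle:::axis_offsets(40L, 40L), 0L)
  # every voxel covered for a range of cases
  for (L in c(24L, 50L, 64L)) for (P in c(8L, 24L)) {
    offs <- petdle:::axis_offsets(L, P)
    covered <- sort(unique(unlist(lapply(offs, function(o) o + 1:P))))
    expect_identical(covered, 1:L)
    expect_equal(offs[length(offs)], L - P)   # last patch ends at the edge
  }
  expect_error(petdle:::axis_offsets(10L, 4L, stride = 0), "stride")
})

test_that("patch extraction and reassembly are exact inverses", {
  vol <- array(runif(20 * 18 * 10), c(20, 18, 10))
  pp <- extract_patches(vol, c(20, 18, 4))
  expect_equal(nrow(pp$offsets), 3L)
  back <- reassemble_patches(pp$patches, pp$offsets, dim(vol))
  expect_equal(back, vol, tolerance = 1e-14)
  # paired volumes get identical placements
  pp2 <- extract_patches(vol * 2, c(20, 18, 4))
  expect_identical(pp$offsets, pp2$offsets)
})

test_that("the best epoch minimises the rank sum with early tie-break", {
  rec <- data.frame(epoch = 0:2,
                    val_mse = c(3, 1, 2),         # ranks 3, 1, 2
                    val_suvmax_mapd = c(2, 30, 10))
  # worked example: MSE ranks (3,1,2), SUV ranks (1,3,2) -> sums (4,4,4)?
  # no: use the spec-style example instead
  rec2 <- data.frame(epoch = 1:3,
                     val_mse = c(1, 2, 3),        # ranks 1, 2, 3
                     val_suvmax_mapd = c(30, 5, 10))  # ranks 3, 1, 2
  expect_equal(select_best_epoch(rec2), 2L)       # rank sums 4, 3, 5
  # single epoch
  expect_equal(select_best_epoch(rec2[1, ]), 1L)
  # dominance: best on both criteria wins
  rec3 <- data.frame(epoch = 0:1, val_mse = c(1, 2),
                     val_suvmax_mapd = c(1, 2))
  expect_equal(select_best_epoch(rec3), 0L)
  # exact ties break towards the earlier epoch
  rec4 <- data.frame(epoch = 0:1, val_mse = c(1, 1),
                     val_suvmax_mapd = c(2, 2))
  expect_equal(select_best_epoch(rec4), 0L)
})

test_that("training on an identity task keeps epoch 0 as the optimum", {
  # target == input: the zero-initialised network is already optimal
  spec <- simple_spec()
  vol <- build_phantom(spec)
  rois <- list(vois = list(voi(c(20, 18, 8), "liver"),
                           voi(c(12, 14, 8), "liver")),
               lesion_centers = list(c(20L, 18L, 8L)))
  pair <- list(input = vol, target = vol)
  m <- dle_train(list(pair), list(pair), list(rois),
                 net_config = network_config(levels = 2, base_channels = 4),
                 train_config = training_config(max_epochs = 2, seed = 1),
                 net_seed = 1)
  expect_equal(m$chosen_epoch, 0L)
  expect_lte(m$record$val_mse[1], min(m$record$val_mse) + 1e-8)
})

test_that("training reduces the loss and logs distinct shuffles", {
  # target = z-filtered (smoothed) input: a learnable denoising task
  set.seed(14)
  mk <- function() {
    v <- array(runif(16 * 16 * 8, 0.5, 3), c(16, 16, 8))
    list(input = pet_volume(v),
         target = pet_volume(z_filter(z_filter(v))))
  }
  pairs <- lapply(1:4, function(i) mk())
  rois <- list(vois = list(voi(c(8, 8, 4), "liver"),
                           voi(c(10, 9, 4), "liver")),
               lesion_centers = list(c(8L, 8L, 4L)))
  m <- dle_train(pairs[1:3], pairs[4], list(rois),
                 net_config = network_config(levels = 2, base_channels = 4),
                 train_config = training_config(max_epochs = 5, batch_size = 2,
                                                seed = 0),
                 net_seed = 2)
  tm <- m$record$train_mse[-1]
  expect_lt(tm[5], tm[1])                       # loss decreases overall
  expect_false(identical(m$permutations[[1]], m$permutations[[2]]))
  # reproducibility: identical seeds give identical records
  m2 <- dle_train(pairs[1:3], pairs[4], list(rois),
                  net_config = network_config(levels = 2, base_channels = 4),
                  train_config = training_config(max_epochs = 5, batch_size = 2,
                                                 seed = 0),
                  net_seed = 2)
  expect_equal(m2$record$train_mse, m$record$train_mse, tolerance = 1e-12)
  expect_equal(m2$record$val_mse, m$record$val_mse, tolerance = 1e-12)
  # checkpoint correctness: re-evaluating the returned model reproduces the
  # recorded validation metrics of the chosen epoch
  vm <- petdle:::val_metrics(m$network, pairs[4], list(rois))
  rec_row <- m$record[m$record$epoch == m$chosen_epoch, ]
  expect_equal(vm$val_mse, rec_row$val_mse, tolerance = 1e-6)
  expect_equal(vm$val_suvmax_mapd, rec_row$val_suvmax_mapd, tolerance = 1e-6)
})

test_that("training records serialise to JSON lines", {
  rec <- data.frame(epoch = 0:1, train_mse = c(NA, 0.5), val_mse = c(1, 0.4),
                    val_suvmax_mapd = c(10, 5), val_liver_noise_pd = c(3, 1),
                    seconds = c(0, 2))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_training_record(rec, path)
  lines <- readLines(path)
  expect_length(lines, 2L)
  parsed <- jsonlite::fromJSON(lines[2])
  expect_equal(parsed$val_mse, 0.4)
})
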