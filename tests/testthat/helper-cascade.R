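# Desk-scale full-cascade protocol, shared by the end-to-end accuracy
# tests: full 400-spectrum cohort on the default grid with the default
# patient-wise split, 16 CWT voices, 112x112 scalogram images, width-8
# ResNet-18 topology, 30 stage-1 epochs and 4 stage-2 epochs at lr 1e-3
# (training from random initialization). Results are memoised per
# contrast level so several tests can share one trained cascade.

.cascade_cache <- new.env(parent = emptyenv())

desk_cascade <- function(contrast = 1, seed = 101L) {
  key <- sprintf("c%s_s%d", format(contrast), seed)
  hit <- .cascade_cache[[key]]
  if (!is.null(hit)) return(hit)
  co <- cohort_config(band_contrast = contrast)
  coh <- generate_cohort(co, seed = seed)
  sp <- cohort_split(coh)
  tr <- normalize_spectra(sp$train)
  te <- normalize_spectra(sp$test)
  m1 <- build_cnn1d(length(tr$wavenumbers), seed = seed + 1L)
  m1 <- train_binary_1d(m1, tr, binary_task("EG1_vs_G2G3"),
                        train_config_1d(epochs = 30L, seed = seed + 1L))
  wp <- wavelet_params(nv = 16L)
  eg1 <- collapse_grades(tr$meta$grade) %in% c("E", "G1")
  imgs <- spectra_to_images(tr[eg1], wp, out_size = 112L)
  m2 <- build_transfer_model(base_width = 8L, n_classes = 2L, seed = seed + 2L)
  m2 <- train_2d(m2, imgs, collapse_grades(tr$meta$grade)[eg1],
                 train_config_2d(epochs = 4L, learning_rate = 1e-3,
                                 batch_size = 16L, seed = seed + 2L,
                                 augment = image_augment_config(resize_to = 112L)))
  casc <- run_cascade(te, m1, m2, wp, out_size = 112L)
  true1 <- ifelse(casc$true %in% c("E", "G1"), "EG1", "G2G3")
  out <- list(
    cascade = casc, stage1 = m1, stage2 = m2, train = tr, test = te,
    stage1_acc = 100 * mean(casc$stage1 == true1),
    cascade_acc = 100 * mean(casc$pred == casc$true)
  )
  .cascade_cache[[key]] <- out
  out
}
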