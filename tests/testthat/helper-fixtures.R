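# Shared fixtures. Heavy objects (a trained model on default-sized synthetic
# fields) are built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# constant-colour image
toy_image <- function(h, w, color = c(255, 255, 255), id = NULL) {
  px <- array(0L, dim = c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- color[ch]
  rgb_image(px, id = id)
}

# scaled-down generator settings for fast unit tests
small_spec <- function(...) {
  args <- utils::modifyList(list(size = c(120, 120), n_nuclei = 8,
                                 n_fibers = 2, bright_fraction = 0.08),
                            list(...))
  do.call(synthetic_spec, args)
}

# fields, annotations and a fitted model on default-sized synthetic fields;
# training fields are the first 10 fields derived from master seed 17
acceptance_seeds <- function(n = 30, master = 17) {
  set.seed(master)
  sample.int(.Machine$integer.max, n)
}

training_set <- function(seeds, spec = synthetic_spec()) {
  fields <- lapply(seq_along(seeds), function(i)
    generate_field(spec, seeds[i], id = sprintf("train_%02d", i)))
  images <- setNames(lapply(fields, `[[`, "image"),
                     vapply(fields, function(f) f$image$id, character(1)))
  ann <- do.call(rbind, lapply(fields, function(f)
    auto_annotate(f$truth, f$image$id)))
  list(fields = fields, images = images, annotations = ann)
}

get_trained_model <- function() {
  if (is.null(.fixtures$model)) {
    ts <- training_set(acceptance_seeds(30)[1:10])
    .fixtures$model <- hemocyte_model(ts$images, ts$annotations)
  }
  .fixtures$model
}

# small trained model on fast fields, for tests that only need "a model"
get_small_model <- function() {
  if (is.null(.fixtures$small_model)) {
    ts <- training_set(1:8 + 500, spec = small_spec(hemocyte_lambda = 4))
    .fixtures$small_model <- hemocyte_model(ts$images, ts$annotations)
  }
  .fixtures$small_model
}
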