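# shared fixtures, all generated in code

# a random point in the interior of the 4-simplex
random_simplex <- function(alpha = 1) {
  x <- rgamma(4, shape = alpha) + 1e-6
  x / sum(x)
}

# relabel colors: new color j is old color perm[j]; counts move so that an
# image's category follows its colors, p_new = p_old[perm]
permute_category_counts <- function(counts, perm) {
  space <- counts$space
  members <- attr(space, "members")
  keys <- vapply(members, paste, "", collapse = ",")
  new_counts <- counts$counts
  for (j in seq_along(members)) {
    old_set <- sort(perm[members[[j]]])
    new_counts[j] <- counts$counts[match(paste(old_set, collapse = ","), keys)]
  }
  category_counts(unname(new_counts), dataset_id = counts$meta$dataset_id,
                  induction_min = counts$meta$induction_min,
                  stage = counts$meta$stage,
                  image_class = counts$meta$image_class)
}

# counts table whose frequencies are (rounded) expected frequencies under the
# model, for self-consistency fits
expected_counts <- function(mu, p, n_images) {
  f <- mixture_category_probs_closed_form(model_params(mu, p))
  counts <- round(f * n_images)
  counts[1] <- counts[1] + (n_images - sum(counts))  # keep the total exact
  category_counts(unname(counts))
}
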