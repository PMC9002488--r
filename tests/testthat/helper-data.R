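# Shared fixtures built in code.

# The published 14-day breakfast worked example: recurrent items
# {latte, muffin}, recurrent meals {{latte, muffin}, {latte}}, strength
# tuple (1, 13/14, 12/14).
example_meals <- function() {
  list(c("latte", "muffin"), "latte", c("latte", "muffin"),
       c("latte", "croissant"), "latte", "latte", c("latte", "muffin"),
       c("latte", "muffin"), "latte", c("latte", "muffin"),
       c("latte", "muffin"), c("muffin", "hot-chocolate"), "latte",
       c("latte", "muffin"))
}

example_sequence <- function() {
  consumption_sequence(
    "1", "breakfast",
    as.Date("2014-09-01") + c(0, 1, 2, 4, 5, 7, 8, 9, 11, 12, 14, 15, 16, 18),
    example_meals())
}

# Random small sequence; uses the ambient RNG state (callers set the seed).
random_sequence <- function(n_max = 15L, vocab = letters[1:6],
                            max_meal = 3L, id = "u", occasion = "any") {
  n <- sample.int(n_max, 1)
  meals <- lapply(seq_len(n), function(t) {
    sample(vocab, sample.int(min(max_meal, length(vocab)), 1))
  })
  dates <- as.Date("2020-01-01") + cumsum(sample(1:3, n, replace = TRUE))
  consumption_sequence(id, occasion, dates, meals)
}

# A small raw diary covering the artifacts the preprocessing filters target.
make_diary <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(individual_id = r[[1]], date = as.Date(r[[2]]),
               occasion = r[[3]], item_text = r[[4]],
               calories = as.numeric(r[[5]]), stringsAsFactors = FALSE)
  }))
}
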