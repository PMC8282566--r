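# shared fixtures, built in code

# flat life table: constant annual death probability at every age
flat_life_table <- function(q) {
  load_life_table(c("age,qx", paste0("65,", q), paste0("105,", q)))
}

# overrides that switch off fracture incidence entirely
zero_incidence_overrides <- function() {
  list(incidence = list(
    hip = list(age_low = 65, age_high = 105, rate = 0),
    vert = list(age_low = 65, age_high = 105, rate = 0)
  ))
}

# degenerate config: nobody fractures, (almost) nobody dies, utility 1,
# no discounting -- closed forms apply
degenerate_config <- function() {
  cfg <- make_toy_config(overrides = c(
    zero_incidence_overrides(),
    list(
      utilities = list(base_by_age = list(age_low = 65, age_high = 105,
                                          utility = 1)),
      econ = list(discount_cost = 0, discount_qaly = 0)
    )
  ))
  attach_life_table(cfg, flat_life_table(0))
}

japan_cfg <- local({
  cache <- NULL
  function(age = 65L) {
    if (is.null(cache)) {
      cache <<- attach_life_table(default_parameters(), japan_like_life_table())
    }
    cfg <- cache
    cfg$start_age <- as.integer(age)
    cfg
  }
})
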