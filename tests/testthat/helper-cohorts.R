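# shared fixtures, built in code

# one fully valid athlete row at development-group-like values
valid_row <- function(id = "a1") {
  data.frame(athlete_id = id, age = 27.4, weight_kg = 79.5,
             stature_cm = 183.8, triceps_mm = 6.1, subscapular_mm = 9.5,
             supraspinal_mm = 6.7, medial_calf_mm = 5.4, arm_girth_cm = 33.1,
             calf_girth_cm = 37.9, humerus_cm = 7.2, femur_cm = 10.2,
             resistance_ohm = 464.3, reactance_ohm = 63.8,
             position = "midfielder")
}

# small linked-mode cohort, memoised per seed for speed
linked_cohort <- local({
  cache <- list()
  function(n = 60, seed = 11) {
    key <- paste(n, seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- generate_cohort(cohort_spec(n = n, seed = seed))
    }
    cache[[key]]
  }
})

# random valid scalar inputs for brute-force oracle checks
runif_mat <- function(n, ranges, seed) {
  set.seed(seed)
  out <- sapply(ranges, function(r) stats::runif(n, r[1], r[2]))
  as.data.frame(out)
}
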