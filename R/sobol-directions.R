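# Primitive polynomials and initial direction numbers (m-values) for the
# first 512 Sobol dimensions, from the standard Joe & Kuo (2008) table.
# poly encodes the polynomial coefficients in binary, including the
# leading and constant terms; m-values are listed up to the polynomial degree.
.sobol_poly <- c(1L, 3L, 7L, 11L, 13L, 19L, 25L, 37L, 41L, 47L, 55L, 59L, 61L, 67L, 91L, 97L, 103L, 109L, 115L, 131L, 137L, 143L, 145L, 157L, 167L, 171L, 185L, 191L, 193L, 203L, 211L, 213L, 229L, 239L, 241L, 247L, 253L, 285L, 299L, 301L, 333L, 351L, 355L, 357L, 361L, 369L, 391L, 397L, 425L, 451L, 463L, 487L, 501L, 529L, 539L, 545L, 557L, 563L, 601L, 607L, 617L, 623L, 631L, 637L, 647L, 661L, 675L, 677L, 687L, 695L, 701L, 719L, 721L, 731L, 757L, 761L, 787L, 789L, 799L, 803L, 817L, 827L, 847L, 859L, 865L, 875L, 877L, 883L, 895L, 901L, 911L, 949L, 953L, 967L, 971L, 973L, 981L, 985L, 995L, 1001L, 1019L, 1033L, 1051L, 1063L, 1069L, 1125L, 1135L, 1153L, 1163L, 1221L, 1239L, 1255L, 1267L, 1279L, 1293L, 1305L, 1315L, 1329L, 1341L, 1347L, 1367L, 1387L, 1413L, 1423L, 1431L, 1441L, 1479L, 1509L, 1527L, 1531L, 1555L, 1557L, 1573L, 1591L, 1603L, 1615L, 1627L, 1657L, 1663L, 1673L, 1717L, 1729L, 1747L, 1759L, 1789L, 1815L, 1821L, 1825L, 1849L, 1863L, 1869L, 1877L, 1881L, 1891L, 1917L, 1933L, 1939L, 1969L, 2011L, 2035L, 2041L, 2053L, 2071L, 2091L, 2093L, 2119L, 2147L, 2149L, 2161L, 2171L, 2189L, 2197L, 2207L, 2217L, 2225L, 2255L, 2257L, 2273L, 2279L, 2283L, 2293L, 2317L, 2323L, 2341L, 2345L, 2363L, 2365L, 2373L, 2377L, 2385L, 2395L, 2419L, 2421L, 2431L, 2435L, 2447L, 2475L, 2477L, 2489L, 2503L, 2521L, 2533L, 2551L, 2561L, 2567L, 2579L, 2581L, 2601L, 2633L, 2657L, 2669L, 2681L, 2687L, 2693L, 2705L, 2717L, 2727L, 2731L, 2739L, 2741L, 2773L, 2783L, 2793L, 2799L, 2801L, 2811L, 2819L, 2825L, 2833L, 2867L, 2879L, 2881L, 2891L, 2905L, 2911L, 2917L, 2927L, 2941L, 2951L, 2955L, 2963L, 2965L, 2991L, 2999L, 3005L, 3017L, 3035L, 3037L, 3047L, 3053L, 3083L, 3085L, 3097L, 3103L, 3159L, 3169L, 3179L, 3187L, 3205L, 3209L, 3223L, 3227L, 3229L, 3251L, 3263L, 3271L, 3277L, 3283L, 3285L, 3299L, 3305L, 3319L, 3331L, 3343L, 3357L, 3367L, 3373L, 3393L, 3399L, 3413L, 3417L, 3427L, 3439L, 3441L, 3475L, 3487L, 3497L, 3515L, 3517L, 3529L, 3543L, 3547L, 3553L, 3559L, 3573L, 3589L, 3613L, 3617L, 3623L, 3627L, 3635L, 3641L, 3655L, 3659L, 3669L, 3679L, 3697L, 3707L, 3709L, 3713L, 3731L, 3743L, 3747L, 3771L, 3791L, 3805L, 3827L, 3833L, 3851L, 3865L, 3889L, 3895L, 3933L, 3947L, 3949L, 3957L, 3971L, 3985L, 3991L, 3995L, 4007L, 4013L, 4021L, 4045L, 4051L, 4069L, 4073L, 4179L, 4201L, 4219L, 4221L, 4249L, 4305L, 4331L, 4359L, 4383L, 4387L, 4411L, 4431L, 4439L, 4449L, 4459L, 4485L, 4531L, 4569L, 4575L, 4621L, 4663L, 4669L, 4711L, 4723L, 4735L, 4793L, 4801L, 4811L, 4879L, 4893L, 4897L, 4921L, 4927L, 4941L, 4977L, 5017L, 5027L, 5033L, 5127L, 5169L, 5175L, 5199L, 5213L, 5223L, 5237L, 5287L, 5293L, 5331L, 5391L, 5405L, 5453L, 5523L, 5573L, 5591L, 5597L, 5611L, 5641L, 5703L, 5717L, 5721L, 5797L, 5821L, 5909L, 5913L, 5955L, 5957L, 6005L, 6025L, 6061L, 6067L, 6079L, 6081L, 6231L, 6237L, 6289L, 6295L, 6329L, 6383L, 6427L, 6453L, 6465L, 6501L, 6523L, 6539L, 6577L, 6589L, 6601L, 6607L, 6631L, 6683L, 6699L, 6707L, 6761L, 6795L, 6865L, 6881L, 6901L, 6923L, 6931L, 6943L, 6999L, 7057L, 7079L, 7103L, 7105L, 7123L, 7173L, 7185L, 7191L, 7207L, 7245L, 7303L, 7327L, 7333L, 7355L, 7365L, 7369L, 7375L, 7411L, 7431L, 7459L, 7491L, 7505L, 7515L, 7541L, 7557L, 7561L, 7701L, 7705L, 7727L, 7749L, 7761L, 7783L, 7795L, 7823L, 7907L, 7953L, 7963L, 7975L, 8049L, 8089L, 8123L, 8125L, 8137L, 8219L, 8231L, 8245L, 8275L, 8293L, 8303L, 8331L, 8333L, 8351L, 8357L, 8367L, 8379L, 8381L, 8387L, 8393L, 8417L, 8435L, 8461L, 8469L, 8489L, 8495L, 8507L, 8515L, 8551L, 8555L, 8569L, 8585L, 8599L, 8605L, 8639L, 8641L)
.sobol_minit <- list(
  c(1L),
  c(1L),
  c(1L, 3L),
  c(1L, 3L, 1L),
  c(1L, 1L, 1L),
  c(1L, 1L, 3L, 3L),
  c(1L, 3L, 5L, 13L),
  c(1L, 1L, 5L, 5L, 17L),
  c(1L, 1L, 5L, 5L, 5L),
  c(1L, 1L, 7L, 11L, 19L),
  c(1L, 1L, 5L, 1L, 1L),
  c(1L, 1L, 1L, 3L, 11L),
  c(1L, 3L, 5L, 5L, 31L),
  c(1L, 3L, 3L, 9L, 7L, 49L),
  c(1L, 1L, 1L, 15L, 21L, 21L),
  c(1L, 3L, 1L, 13L, 27L, 49L),
  c(1L, 1L, 1L, 15L, 7L, 5L),
  c(1L, 3L, 1L, 15L, 13L, 25L),
  c(1L, 1L, 5L, 5L, 19L, 61L),
  c(1L, 3L, 7L, 11L, 23L, 15L, 103L),
  c(1L, 3L, 7L, 13L, 13L, 15L, 69L),
  c(1L, 1L, 3L, 13L, 7L, 35L, 63L),
  c(1L, 3L, 5L, 9L, 1L, 25L, 53L),
  c(1L, 3L, 1L, 13L, 9L, 35L, 107L),
  c(1L, 3L, 1L, 5L, 27L, 61L, 31L),
  c(1L, 1L, 5L, 11L, 19L, 41L, 61L),
  c(1L, 3L, 5L, 3L, 3L, 13L, 69L),
  c(1L, 1L, 7L, 13L, 1L, 19L, 1L),
  c(1L, 3L, 7L, 5L, 13L, 19L, 59L),
  c(1L, 1L, 3L, 9L, 25L, 29L, 41L),
  c(1L, 3L, 5L, 13L, 23L, 1L, 55L),
  c(1L, 3L, 7L, 3L, 13L, 59L, 17L),
  c(1L, 3L, 1L, 3L, 5L, 53L, 69L),
  c(1L, 1L, 5L, 5L, 23L, 33L, 13L),
  c(1L, 1L, 7L, 7L, 1L, 61L, 123L),
  c(1L, 1L, 7L, 9L, 13L, 61L, 49L),
  c(1L, 3L, 3L, 5L, 3L, 55L, 33L),
  c(1L, 3L, 1L, 15L, 31L, 13L, 49L, 245L),
  c(1L, 3L, 5L, 15L, 31L, 59L, 63L, 97L),
  c(1L, 3L, 1L, 11L, 11L, 11L, 77L, 249L),
  c(1L, 3L, 1L, 11L, 27L, 43L, 71L, 9L),
  c(1L, 1L, 7L, 15L, 21L, 11L, 81L, 45L),
  c(1L, 3L, 7L, 3L, 25L, 31L, 65L, 79L),
  c(1L, 3L, 1L, 1L, 19L, 11L, 3L, 205L),
  c(1L, 1L, 5L, 9L, 19L, 21L, 29L, 157L),
  c(1L, 3L, 7L, 11L, 1L, 33L, 89L, 185L),
  c(1L, 3L, 3L, 3L, 15L, 9L, 79L, 71L),
  c(1L, 3L, 7L, 11L, 15L, 39L, 119L, 27L),
  c(1L, 1L, 3L, 1L, 11L, 31L, 97L, 225L),
  c(1L, 1L, 1L, 3L, 23L, 43L, 57L, 177L),
  c(1L, 3L, 7L, 7L, 17L, 17L, 37L, 71L),
  c(1L, 3L, 1L, 5L, 27L, 63L, 123L, 213L),
  c(1L, 1L, 3L, 5L, 11L, 43L, 53L, 133L),
  c(1L, 3L, 5L, 5L, 29L, 17L, 47L, 173L, 479L),
  c(1L, 3L, 3L, 11L, 3L, 1L, 109L, 9L, 69L),
  c(1L, 1L, 1L, 5L, 17L, 39L, 23L, 5L, 343L),
  c(1L, 3L, 1L, 5L, 25L, 15L, 31L, 103L, 499L),
  c(1L, 1L, 1L, 11L, 11L, 17L, 63L, 105L, 183L),
  c(1L, 1L, 5L, 11L, 9L, 29L, 97L, 231L, 363L),
  c(1L, 1L, 5L, 15L, 19L, 45L, 41L, 7L, 383L),
  c(1L, 3L, 7L, 7L, 31L, 19L, 83L, 137L, 221L),
  c(1L, 1L, 1L, 3L, 23L, 15L, 111L, 223L, 83L),
  c(1L, 1L, 5L, 13L, 31L, 15L, 55L, 25L, 161L),
  c(1L, 1L, 3L, 13L, 25L, 47L, 39L, 87L, 257L),
  c(1L, 1L, 1L, 11L, 21L, 53L, 125L, 249L, 293L),
  c(1L, 1L, 7L, 11L, 11L, 7L, 57L, 79L, 323L),
  c(1L, 1L, 5L, 5L, 17L, 13L, 81L, 3L, 131L),
  c(1L, 1L, 7L, 13L, 23L, 7L, 65L, 251L, 475L),
  c(1L, 3L, 5L, 1L, 9L, 43L, 3L, 149L, 11L),
  c(1L, 1L, 3L, 13L, 31L, 13L, 13L, 255L, 487L),
  c(1L, 3L, 3L, 1L, 5L, 63L, 89L, 91L, 127L),
  c(1L, 1L, 3L, 3L, 1L, 19L, 123L, 127L, 237L),
  c(1L, 1L, 5L, 7L, 23L, 31L, 37L, 243L, 289L),
  c(1L, 1L, 5L, 11L, 17L, 53L, 117L, 183L, 491L),
  c(1L, 1L, 1L, 5L, 1L, 13L, 13L, 209L, 345L),
  c(1L, 1L, 3L, 15L, 1L, 57L, 115L, 7L, 33L),
  c(1L, 3L, 1L, 11L, 7L, 43L, 81L, 207L, 175L),
  c(1L, 3L, 1L, 1L, 15L, 27L, 63L, 255L, 49L),
  c(1L, 3L, 5L, 3L, 27L, 61L, 105L, 171L, 305L),
  c(1L, 1L, 5L, 3L, 1L, 3L, 57L, 249L, 149L),
  c(1L, 1L, 3L, 5L, 5L, 57L, 15L, 13L, 159L),
  c(1L, 1L, 1L, 11L, 7L, 11L, 105L, 141L, 225L),
  c(1L, 3L, 3L, 5L, 27L, 59L, 121L, 101L, 271L),
  c(1L, 3L, 5L, 9L, 11L, 49L, 51L, 59L, 115L),
  c(1L, 1L, 7L, 1L, 23L, 45L, 125L, 71L, 419L),
  c(1L, 1L, 3L, 5L, 23L, 5L, 105L, 109L, 75L),
  c(1L, 1L, 7L, 15L, 7L, 11L, 67L, 121L, 453L),
  c(1L, 3L, 7L, 3L, 9L, 13L, 31L, 27L, 449L),
  c(1L, 3L, 1L, 15L, 19L, 39L, 39L, 89L, 15L),
  c(1L, 1L, 1L, 1L, 1L, 33L, 73L, 145L, 379L),
  c(1L, 3L, 1L, 15L, 15L, 43L, 29L, 13L, 483L),
  c(1L, 1L, 7L, 3L, 19L, 27L, 85L, 131L, 431L),
  c(1L, 3L, 3L, 3L, 5L, 35L, 23L, 195L, 349L),
  c(1L, 3L, 3L, 7L, 9L, 27L, 39L, 59L, 297L),
  c(1L, 1L, 3L, 9L, 11L, 17L, 13L, 241L, 157L),
  c(1L, 3L, 7L, 15L, 25L, 57L, 33L, 189L, 213L),
  c(1L, 1L, 7L, 1L, 9L, 55L, 73L, 83L, 217L),
  c(1L, 3L, 3L, 13L, 19L, 27L, 23L, 113L, 249L),
  c(1L, 3L, 5L, 3L, 23L, 43L, 3L, 253L, 479L),
  c(1L, 1L, 5L, 5L, 11L, 5L, 45L, 117L, 217L),
  c(1L, 3L, 3L, 7L, 29L, 37L, 33L, 123L, 147L),
  c(1L, 3L, 1L, 15L, 5L, 5L, 37L, 227L, 223L, 459L),
  c(1L, 1L, 7L, 5L, 5L, 39L, 63L, 255L, 135L, 487L),
  c(1L, 3L, 1L, 7L, 9L, 7L, 87L, 249L, 217L, 599L),
  c(1L, 1L, 3L, 13L, 9L, 47L, 7L, 225L, 363L, 247L),
  c(1L, 3L, 7L, 13L, 19L, 13L, 9L, 67L, 9L, 737L),
  c(1L, 3L, 5L, 5L, 19L, 59L, 7L, 41L, 319L, 677L),
  c(1L, 1L, 5L, 3L, 31L, 63L, 15L, 43L, 207L, 789L),
  c(1L, 1L, 7L, 9L, 13L, 39L, 3L, 47L, 497L, 169L),
  c(1L, 3L, 1L, 7L, 21L, 17L, 97L, 19L, 415L, 905L),
  c(1L, 3L, 7L, 1L, 3L, 31L, 71L, 111L, 165L, 127L),
  c(1L, 1L, 5L, 11L, 1L, 61L, 83L, 119L, 203L, 847L),
  c(1L, 3L, 3L, 13L, 9L, 61L, 19L, 97L, 47L, 35L),
  c(1L, 1L, 7L, 7L, 15L, 29L, 63L, 95L, 417L, 469L),
  c(1L, 3L, 1L, 9L, 25L, 9L, 71L, 57L, 213L, 385L),
  c(1L, 3L, 5L, 13L, 31L, 47L, 101L, 57L, 39L, 341L),
  c(1L, 1L, 3L, 3L, 31L, 57L, 125L, 173L, 365L, 551L),
  c(1L, 3L, 7L, 1L, 13L, 57L, 67L, 157L, 451L, 707L),
  c(1L, 1L, 1L, 7L, 21L, 13L, 105L, 89L, 429L, 965L),
  c(1L, 1L, 5L, 9L, 17L, 51L, 45L, 119L, 157L, 141L),
  c(1L, 3L, 7L, 7L, 13L, 45L, 91L, 9L, 129L, 741L),
  c(1L, 3L, 7L, 1L, 23L, 57L, 67L, 141L, 151L, 571L),
  c(1L, 1L, 3L, 11L, 17L, 47L, 93L, 107L, 375L, 157L),
  c(1L, 3L, 3L, 5L, 11L, 21L, 43L, 51L, 169L, 915L),
  c(1L, 1L, 5L, 3L, 15L, 55L, 101L, 67L, 455L, 625L),
  c(1L, 3L, 5L, 9L, 1L, 23L, 29L, 47L, 345L, 595L),
  c(1L, 3L, 7L, 7L, 5L, 49L, 29L, 155L, 323L, 589L),
  c(1L, 3L, 3L, 7L, 5L, 41L, 127L, 61L, 261L, 717L),
  c(1L, 3L, 7L, 7L, 17L, 23L, 117L, 67L, 129L, 1009L),
  c(1L, 1L, 3L, 13L, 11L, 39L, 21L, 207L, 123L, 305L),
  c(1L, 1L, 3L, 9L, 29L, 3L, 95L, 47L, 231L, 73L),
  c(1L, 3L, 1L, 9L, 1L, 29L, 117L, 21L, 441L, 259L),
  c(1L, 3L, 1L, 13L, 21L, 39L, 125L, 211L, 439L, 723L),
  c(1L, 1L, 7L, 3L, 17L, 63L, 115L, 89L, 49L, 773L),
  c(1L, 3L, 7L, 13L, 11L, 33L, 101L, 107L, 63L, 73L),
  c(1L, 1L, 5L, 5L, 13L, 57L, 63L, 135L, 437L, 177L),
  c(1L, 1L, 3L, 7L, 27L, 63L, 93L, 47L, 417L, 483L),
  c(1L, 1L, 3L, 1L, 23L, 29L, 1L, 191L, 49L, 23L),
  c(1L, 1L, 3L, 15L, 25L, 55L, 9L, 101L, 219L, 607L),
  c(1L, 3L, 1L, 7L, 7L, 19L, 51L, 251L, 393L, 307L),
  c(1L, 3L, 3L, 3L, 25L, 55L, 17L, 75L, 337L, 3L),
  c(1L, 1L, 1L, 13L, 25L, 17L, 65L, 45L, 479L, 413L),
  c(1L, 1L, 7L, 7L, 27L, 49L, 99L, 161L, 213L, 727L),
  c(1L, 3L, 5L, 1L, 23L, 5L, 43L, 41L, 251L, 857L),
  c(1L, 3L, 3L, 7L, 11L, 61L, 39L, 87L, 383L, 835L),
  c(1L, 1L, 3L, 15L, 13L, 7L, 29L, 7L, 505L, 923L),
  c(1L, 3L, 7L, 1L, 5L, 31L, 47L, 157L, 445L, 501L),
  c(1L, 1L, 3L, 7L, 1L, 43L, 9L, 147L, 115L, 605L),
  c(1L, 3L, 3L, 13L, 5L, 1L, 119L, 211L, 455L, 1001L),
  c(1L, 1L, 3L, 5L, 13L, 19L, 3L, 243L, 75L, 843L),
  c(1L, 3L, 7L, 7L, 1L, 19L, 91L, 249L, 357L, 589L),
  c(1L, 1L, 1L, 9L, 1L, 25L, 109L, 197L, 279L, 411L),
  c(1L, 3L, 1L, 15L, 23L, 57L, 59L, 135L, 191L, 75L),
  c(1L, 1L, 5L, 15L, 29L, 21L, 39L, 253L, 383L, 349L),
  c(1L, 3L, 3L, 5L, 19L, 45L, 61L, 151L, 199L, 981L),
  c(1L, 3L, 5L, 13L, 9L, 61L, 107L, 141L, 141L, 1L),
  c(1L, 3L, 1L, 11L, 27L, 25L, 85L, 105L, 309L, 979L),
  c(1L, 3L, 3L, 11L, 19L, 7L, 115L, 223L, 349L, 43L),
  c(1L, 1L, 7L, 9L, 21L, 39L, 123L, 21L, 275L, 927L),
  c(1L, 1L, 7L, 13L, 15L, 41L, 47L, 243L, 303L, 437L),
  c(1L, 1L, 1L, 7L, 7L, 3L, 15L, 99L, 409L, 719L),
  c(1L, 3L, 3L, 15L, 27L, 49L, 113L, 123L, 113L, 67L, 469L),
  c(1L, 3L, 7L, 11L, 3L, 23L, 87L, 169L, 119L, 483L, 199L),
  c(1L, 1L, 5L, 15L, 7L, 17L, 109L, 229L, 179L, 213L, 741L),
  c(1L, 1L, 5L, 13L, 11L, 17L, 25L, 135L, 403L, 557L, 1433L),
  c(1L, 3L, 1L, 1L, 1L, 61L, 67L, 215L, 189L, 945L, 1243L),
  c(1L, 1L, 7L, 13L, 17L, 33L, 9L, 221L, 429L, 217L, 1679L),
  c(1L, 1L, 3L, 11L, 27L, 3L, 15L, 93L, 93L, 865L, 1049L),
  c(1L, 3L, 7L, 7L, 25L, 41L, 121L, 35L, 373L, 379L, 1547L),
  c(1L, 3L, 3L, 9L, 11L, 35L, 45L, 205L, 241L, 9L, 59L),
  c(1L, 3L, 1L, 7L, 3L, 51L, 7L, 177L, 53L, 975L, 89L),
  c(1L, 1L, 3L, 5L, 27L, 1L, 113L, 231L, 299L, 759L, 861L),
  c(1L, 3L, 3L, 15L, 25L, 29L, 5L, 255L, 139L, 891L, 2031L),
  c(1L, 3L, 1L, 1L, 13L, 9L, 109L, 193L, 419L, 95L, 17L),
  c(1L, 1L, 7L, 9L, 3L, 7L, 29L, 41L, 135L, 839L, 867L),
  c(1L, 1L, 7L, 9L, 25L, 49L, 123L, 217L, 113L, 909L, 215L),
  c(1L, 1L, 7L, 3L, 23L, 15L, 43L, 133L, 217L, 327L, 901L),
  c(1L, 1L, 3L, 3L, 13L, 53L, 63L, 123L, 477L, 711L, 1387L),
  c(1L, 1L, 3L, 15L, 7L, 29L, 75L, 119L, 181L, 957L, 247L),
  c(1L, 1L, 1L, 11L, 27L, 25L, 109L, 151L, 267L, 99L, 1461L),
  c(1L, 3L, 7L, 15L, 5L, 5L, 53L, 145L, 11L, 725L, 1501L),
  c(1L, 3L, 7L, 1L, 9L, 43L, 71L, 229L, 157L, 607L, 1835L),
  c(1L, 3L, 3L, 13L, 25L, 1L, 5L, 27L, 471L, 349L, 127L),
  c(1L, 1L, 1L, 1L, 23L, 37L, 9L, 221L, 269L, 897L, 1685L),
  c(1L, 1L, 3L, 3L, 31L, 29L, 51L, 19L, 311L, 553L, 1969L),
  c(1L, 3L, 7L, 5L, 5L, 55L, 17L, 39L, 475L, 671L, 1529L),
  c(1L, 1L, 7L, 1L, 1L, 35L, 47L, 27L, 437L, 395L, 1635L),
  c(1L, 1L, 7L, 3L, 13L, 23L, 43L, 135L, 327L, 139L, 389L),
  c(1L, 3L, 7L, 3L, 9L, 25L, 91L, 25L, 429L, 219L, 513L),
  c(1L, 1L, 3L, 5L, 13L, 29L, 119L, 201L, 277L, 157L, 2043L),
  c(1L, 3L, 5L, 3L, 29L, 57L, 13L, 17L, 167L, 739L, 1031L),
  c(1L, 3L, 3L, 5L, 29L, 21L, 95L, 27L, 255L, 679L, 1531L),
  c(1L, 3L, 7L, 15L, 9L, 5L, 21L, 71L, 61L, 961L, 1201L),
  c(1L, 3L, 5L, 13L, 15L, 57L, 33L, 93L, 459L, 867L, 223L),
  c(1L, 1L, 1L, 15L, 17L, 43L, 127L, 191L, 67L, 177L, 1073L),
  c(1L, 1L, 1L, 15L, 23L, 7L, 21L, 199L, 75L, 293L, 1611L),
  c(1L, 3L, 7L, 13L, 15L, 39L, 21L, 149L, 65L, 741L, 319L),
  c(1L, 3L, 7L, 11L, 23L, 13L, 101L, 89L, 277L, 519L, 711L),
  c(1L, 3L, 7L, 15L, 19L, 27L, 85L, 203L, 441L, 97L, 1895L),
  c(1L, 3L, 1L, 3L, 29L, 25L, 21L, 155L, 11L, 191L, 197L),
  c(1L, 1L, 7L, 5L, 27L, 11L, 81L, 101L, 457L, 675L, 1687L),
  c(1L, 3L, 1L, 5L, 25L, 5L, 65L, 193L, 41L, 567L, 781L),
  c(1L, 3L, 1L, 5L, 11L, 15L, 113L, 77L, 411L, 695L, 1111L),
  c(1L, 1L, 3L, 9L, 11L, 53L, 119L, 171L, 55L, 297L, 509L),
  c(1L, 1L, 1L, 1L, 11L, 39L, 113L, 139L, 165L, 347L, 595L),
  c(1L, 3L, 7L, 11L, 9L, 17L, 101L, 13L, 81L, 325L, 1733L),
  c(1L, 3L, 1L, 1L, 21L, 43L, 115L, 9L, 113L, 907L, 645L),
  c(1L, 1L, 7L, 3L, 9L, 25L, 117L, 197L, 159L, 471L, 475L),
  c(1L, 3L, 1L, 9L, 11L, 21L, 57L, 207L, 485L, 613L, 1661L),
  c(1L, 1L, 7L, 7L, 27L, 55L, 49L, 223L, 89L, 85L, 1523L),
  c(1L, 1L, 5L, 3L, 19L, 41L, 45L, 51L, 447L, 299L, 1355L),
  c(1L, 3L, 1L, 13L, 1L, 33L, 117L, 143L, 313L, 187L, 1073L),
  c(1L, 1L, 7L, 7L, 5L, 11L, 65L, 97L, 377L, 377L, 1501L),
  c(1L, 3L, 1L, 1L, 21L, 35L, 95L, 65L, 99L, 23L, 1239L),
  c(1L, 1L, 5L, 9L, 3L, 37L, 95L, 167L, 115L, 425L, 867L),
  c(1L, 3L, 3L, 13L, 1L, 37L, 27L, 189L, 81L, 679L, 773L),
  c(1L, 1L, 3L, 11L, 1L, 61L, 99L, 233L, 429L, 969L, 49L),
  c(1L, 1L, 1L, 7L, 25L, 63L, 99L, 165L, 245L, 793L, 1143L),
  c(1L, 1L, 5L, 11L, 11L, 43L, 55L, 65L, 71L, 283L, 273L),
  c(1L, 1L, 5L, 5L, 9L, 3L, 101L, 251L, 355L, 379L, 1611L),
  c(1L, 1L, 1L, 15L, 21L, 63L, 85L, 99L, 49L, 749L, 1335L),
  c(1L, 1L, 5L, 13L, 27L, 9L, 121L, 43L, 255L, 715L, 289L),
  c(1L, 3L, 1L, 5L, 27L, 19L, 17L, 223L, 77L, 571L, 1415L),
  c(1L, 1L, 5L, 3L, 13L, 59L, 125L, 251L, 195L, 551L, 1737L),
  c(1L, 3L, 3L, 15L, 13L, 27L, 49L, 105L, 389L, 971L, 755L),
  c(1L, 3L, 5L, 15L, 23L, 43L, 35L, 107L, 447L, 763L, 253L),
  c(1L, 3L, 5L, 11L, 21L, 3L, 17L, 39L, 497L, 407L, 611L),
  c(1L, 1L, 7L, 13L, 15L, 31L, 113L, 17L, 23L, 507L, 1995L),
  c(1L, 1L, 7L, 15L, 3L, 15L, 31L, 153L, 423L, 79L, 503L),
  c(1L, 1L, 7L, 9L, 19L, 25L, 23L, 171L, 505L, 923L, 1989L),
  c(1L, 1L, 5L, 9L, 21L, 27L, 121L, 223L, 133L, 87L, 697L),
  c(1L, 1L, 5L, 5L, 9L, 19L, 107L, 99L, 319L, 765L, 1461L),
  c(1L, 1L, 3L, 3L, 19L, 25L, 3L, 101L, 171L, 729L, 187L),
  c(1L, 1L, 3L, 1L, 13L, 23L, 85L, 93L, 291L, 209L, 37L),
  c(1L, 1L, 1L, 15L, 25L, 25L, 77L, 253L, 333L, 947L, 1073L),
  c(1L, 1L, 3L, 9L, 17L, 29L, 55L, 47L, 255L, 305L, 2037L),
  c(1L, 3L, 3L, 9L, 29L, 63L, 9L, 103L, 489L, 939L, 1523L),
  c(1L, 3L, 7L, 15L, 7L, 31L, 89L, 175L, 369L, 339L, 595L),
  c(1L, 3L, 7L, 13L, 25L, 5L, 71L, 207L, 251L, 367L, 665L),
  c(1L, 3L, 3L, 3L, 21L, 25L, 75L, 35L, 31L, 321L, 1603L),
  c(1L, 1L, 1L, 9L, 11L, 1L, 65L, 5L, 11L, 329L, 535L),
  c(1L, 1L, 5L, 3L, 19L, 13L, 17L, 43L, 379L, 485L, 383L),
  c(1L, 3L, 5L, 13L, 13L, 9L, 85L, 147L, 489L, 787L, 1133L),
  c(1L, 3L, 1L, 1L, 5L, 51L, 37L, 129L, 195L, 297L, 1783L),
  c(1L, 1L, 3L, 15L, 19L, 57L, 59L, 181L, 455L, 697L, 2033L),
  c(1L, 3L, 7L, 1L, 27L, 9L, 65L, 145L, 325L, 189L, 201L),
  c(1L, 3L, 1L, 15L, 31L, 23L, 19L, 5L, 485L, 581L, 539L),
  c(1L, 1L, 7L, 13L, 11L, 15L, 65L, 83L, 185L, 847L, 831L),
  c(1L, 3L, 5L, 7L, 7L, 55L, 73L, 15L, 303L, 511L, 1905L),
  c(1L, 3L, 5L, 9L, 7L, 21L, 45L, 15L, 397L, 385L, 597L),
  c(1L, 3L, 7L, 3L, 23L, 13L, 73L, 221L, 511L, 883L, 1265L),
  c(1L, 1L, 3L, 11L, 1L, 51L, 73L, 185L, 33L, 975L, 1441L),
  c(1L, 3L, 3L, 9L, 19L, 59L, 21L, 39L, 339L, 37L, 143L),
  c(1L, 1L, 7L, 1L, 31L, 33L, 19L, 167L, 117L, 635L, 639L),
  c(1L, 1L, 1L, 3L, 5L, 13L, 59L, 83L, 355L, 349L, 1967L),
  c(1L, 1L, 1L, 5L, 19L, 3L, 53L, 133L, 97L, 863L, 983L),
  c(1L, 3L, 1L, 13L, 9L, 41L, 91L, 105L, 173L, 97L, 625L),
  c(1L, 1L, 5L, 3L, 7L, 49L, 115L, 133L, 71L, 231L, 1063L),
  c(1L, 1L, 7L, 5L, 17L, 43L, 47L, 45L, 497L, 547L, 757L),
  c(1L, 3L, 5L, 15L, 21L, 61L, 123L, 191L, 249L, 31L, 631L),
  c(1L, 3L, 7L, 9L, 17L, 7L, 11L, 185L, 127L, 169L, 1951L),
  c(1L, 1L, 5L, 13L, 11L, 11L, 9L, 49L, 29L, 125L, 791L),
  c(1L, 1L, 1L, 15L, 31L, 41L, 13L, 167L, 273L, 429L, 57L),
  c(1L, 3L, 5L, 3L, 27L, 7L, 35L, 209L, 65L, 265L, 1393L),
  c(1L, 3L, 1L, 13L, 31L, 19L, 53L, 143L, 135L, 9L, 1021L),
  c(1L, 1L, 7L, 13L, 31L, 5L, 115L, 153L, 143L, 957L, 623L),
  c(1L, 1L, 5L, 11L, 25L, 19L, 29L, 31L, 297L, 943L, 443L),
  c(1L, 3L, 3L, 5L, 21L, 11L, 127L, 81L, 479L, 25L, 699L),
  c(1L, 1L, 3L, 11L, 25L, 31L, 97L, 19L, 195L, 781L, 705L),
  c(1L, 1L, 5L, 5L, 31L, 11L, 75L, 207L, 197L, 885L, 2037L),
  c(1L, 1L, 1L, 11L, 9L, 23L, 29L, 231L, 307L, 17L, 1497L),
  c(1L, 1L, 5L, 11L, 11L, 43L, 111L, 233L, 307L, 523L, 1259L),
  c(1L, 1L, 7L, 5L, 1L, 21L, 107L, 229L, 343L, 933L, 217L),
  c(1L, 1L, 1L, 11L, 3L, 21L, 125L, 131L, 405L, 599L, 1469L),
  c(1L, 3L, 5L, 5L, 9L, 39L, 33L, 81L, 389L, 151L, 811L),
  c(1L, 1L, 7L, 7L, 7L, 1L, 59L, 223L, 265L, 529L, 2021L),
  c(1L, 3L, 1L, 3L, 9L, 23L, 85L, 181L, 47L, 265L, 49L),
  c(1L, 3L, 5L, 11L, 19L, 23L, 9L, 7L, 157L, 299L, 1983L),
  c(1L, 3L, 1L, 5L, 15L, 5L, 21L, 105L, 29L, 339L, 1041L),
  c(1L, 1L, 1L, 1L, 5L, 33L, 65L, 85L, 111L, 705L, 479L),
  c(1L, 1L, 1L, 7L, 9L, 35L, 77L, 87L, 151L, 321L, 101L),
  c(1L, 1L, 5L, 7L, 17L, 1L, 51L, 197L, 175L, 811L, 1229L),
  c(1L, 3L, 3L, 15L, 23L, 37L, 85L, 185L, 239L, 543L, 731L),
  c(1L, 3L, 1L, 7L, 7L, 55L, 111L, 109L, 289L, 439L, 243L),
  c(1L, 1L, 7L, 11L, 17L, 53L, 35L, 217L, 259L, 853L, 1667L),
  c(1L, 3L, 1L, 9L, 1L, 63L, 87L, 17L, 73L, 565L, 1091L),
  c(1L, 1L, 3L, 3L, 11L, 41L, 1L, 57L, 295L, 263L, 1029L),
  c(1L, 1L, 5L, 1L, 27L, 45L, 109L, 161L, 411L, 421L, 1395L),
  c(1L, 3L, 5L, 11L, 25L, 35L, 47L, 191L, 339L, 417L, 1727L),
  c(1L, 1L, 5L, 15L, 21L, 1L, 93L, 251L, 351L, 217L, 1767L),
  c(1L, 3L, 3L, 11L, 3L, 7L, 75L, 155L, 313L, 211L, 491L),
  c(1L, 3L, 3L, 5L, 11L, 9L, 101L, 161L, 453L, 913L, 1067L),
  c(1L, 1L, 3L, 1L, 15L, 45L, 127L, 141L, 163L, 727L, 1597L),
  c(1L, 3L, 3L, 7L, 1L, 33L, 63L, 73L, 73L, 341L, 1691L),
  c(1L, 3L, 5L, 13L, 15L, 39L, 53L, 235L, 77L, 99L, 949L),
  c(1L, 1L, 5L, 13L, 31L, 17L, 97L, 13L, 215L, 301L, 1927L),
  c(1L, 1L, 7L, 1L, 1L, 37L, 91L, 93L, 441L, 251L, 1131L),
  c(1L, 3L, 7L, 9L, 25L, 5L, 105L, 69L, 81L, 943L, 1459L),
  c(1L, 3L, 7L, 11L, 31L, 43L, 13L, 209L, 27L, 1017L, 501L),
  c(1L, 1L, 7L, 15L, 1L, 33L, 31L, 233L, 161L, 507L, 387L),
  c(1L, 3L, 3L, 5L, 5L, 53L, 33L, 177L, 503L, 627L, 1927L),
  c(1L, 1L, 7L, 11L, 7L, 61L, 119L, 31L, 457L, 229L, 1875L),
  c(1L, 1L, 5L, 15L, 19L, 5L, 53L, 201L, 157L, 885L, 1057L),
  c(1L, 3L, 7L, 9L, 1L, 35L, 51L, 113L, 249L, 425L, 1009L),
  c(1L, 3L, 5L, 7L, 21L, 53L, 37L, 155L, 119L, 345L, 631L),
  c(1L, 3L, 5L, 7L, 15L, 31L, 109L, 69L, 503L, 595L, 1879L),
  c(1L, 3L, 3L, 1L, 25L, 35L, 65L, 131L, 403L, 705L, 503L),
  c(1L, 3L, 7L, 7L, 19L, 33L, 11L, 153L, 45L, 633L, 499L),
  c(1L, 3L, 3L, 5L, 11L, 3L, 29L, 93L, 487L, 33L, 703L),
  c(1L, 1L, 3L, 15L, 21L, 53L, 107L, 179L, 387L, 927L, 1757L),
  c(1L, 1L, 3L, 7L, 21L, 45L, 51L, 147L, 175L, 317L, 361L),
  c(1L, 1L, 1L, 7L, 7L, 13L, 15L, 243L, 269L, 795L, 1965L),
  c(1L, 1L, 3L, 5L, 19L, 33L, 57L, 115L, 443L, 537L, 627L),
  c(1L, 3L, 3L, 9L, 3L, 39L, 25L, 61L, 185L, 717L, 1049L),
  c(1L, 3L, 7L, 3L, 7L, 37L, 107L, 153L, 7L, 269L, 1581L),
  c(1L, 1L, 7L, 3L, 7L, 41L, 91L, 41L, 145L, 489L, 1245L),
  c(1L, 1L, 5L, 9L, 7L, 7L, 105L, 81L, 403L, 407L, 283L),
  c(1L, 1L, 7L, 9L, 27L, 55L, 29L, 77L, 193L, 963L, 949L),
  c(1L, 1L, 5L, 3L, 25L, 51L, 107L, 63L, 403L, 917L, 815L),
  c(1L, 1L, 7L, 3L, 7L, 61L, 19L, 51L, 457L, 599L, 535L),
  c(1L, 3L, 7L, 1L, 23L, 51L, 105L, 153L, 239L, 215L, 1847L),
  c(1L, 1L, 3L, 5L, 27L, 23L, 79L, 49L, 495L, 45L, 1935L),
  c(1L, 1L, 1L, 11L, 11L, 47L, 55L, 133L, 495L, 999L, 1461L),
  c(1L, 1L, 3L, 15L, 27L, 51L, 93L, 17L, 355L, 763L, 1675L),
  c(1L, 3L, 1L, 3L, 1L, 3L, 79L, 119L, 499L, 17L, 995L),
  c(1L, 1L, 1L, 1L, 15L, 43L, 45L, 17L, 167L, 973L, 799L),
  c(1L, 1L, 1L, 3L, 27L, 49L, 89L, 29L, 483L, 913L, 2023L),
  c(1L, 1L, 3L, 3L, 5L, 11L, 75L, 7L, 41L, 851L, 611L),
  c(1L, 3L, 1L, 3L, 7L, 57L, 39L, 123L, 257L, 283L, 507L),
  c(1L, 3L, 3L, 11L, 27L, 23L, 113L, 229L, 187L, 299L, 133L),
  c(1L, 1L, 3L, 13L, 9L, 63L, 101L, 77L, 451L, 169L, 337L),
  c(1L, 3L, 7L, 3L, 3L, 59L, 45L, 195L, 229L, 415L, 409L),
  c(1L, 3L, 5L, 3L, 11L, 19L, 71L, 93L, 43L, 857L, 369L),
  c(1L, 3L, 7L, 9L, 19L, 33L, 115L, 19L, 241L, 703L, 247L),
  c(1L, 3L, 5L, 11L, 5L, 35L, 21L, 155L, 463L, 1005L, 1073L),
  c(1L, 3L, 7L, 3L, 25L, 15L, 109L, 83L, 93L, 69L, 1189L),
  c(1L, 3L, 5L, 7L, 5L, 21L, 93L, 133L, 135L, 167L, 903L),
  c(1L, 1L, 7L, 7L, 3L, 59L, 121L, 161L, 285L, 815L, 1769L, 3705L),
  c(1L, 3L, 1L, 1L, 3L, 47L, 103L, 171L, 381L, 609L, 185L, 373L),
  c(1L, 3L, 3L, 15L, 23L, 33L, 107L, 131L, 441L, 445L, 689L, 2059L),
  c(1L, 3L, 3L, 11L, 7L, 53L, 101L, 167L, 435L, 803L, 1255L, 3781L),
  c(1L, 1L, 5L, 11L, 15L, 59L, 41L, 19L, 135L, 835L, 1263L, 505L),
  c(1L, 1L, 7L, 11L, 21L, 49L, 23L, 219L, 127L, 961L, 1065L, 385L),
  c(1L, 3L, 5L, 15L, 7L, 47L, 117L, 217L, 45L, 731L, 1639L, 733L),
  c(1L, 1L, 7L, 11L, 27L, 57L, 91L, 87L, 81L, 35L, 1269L, 1007L),
  c(1L, 1L, 3L, 11L, 15L, 37L, 53L, 219L, 193L, 937L, 1899L, 3733L),
  c(1L, 3L, 5L, 3L, 13L, 11L, 27L, 19L, 199L, 393L, 965L, 2195L),
  c(1L, 3L, 1L, 3L, 5L, 1L, 37L, 173L, 413L, 1023L, 553L, 409L),
  c(1L, 3L, 1L, 7L, 15L, 29L, 123L, 95L, 255L, 373L, 1799L, 3841L),
  c(1L, 3L, 5L, 13L, 21L, 57L, 51L, 17L, 511L, 195L, 1157L, 1831L),
  c(1L, 1L, 1L, 15L, 29L, 19L, 7L, 73L, 295L, 519L, 587L, 3523L),
  c(1L, 1L, 5L, 13L, 13L, 35L, 115L, 191L, 123L, 535L, 717L, 1661L),
  c(1L, 3L, 3L, 5L, 23L, 21L, 47L, 251L, 379L, 921L, 1119L, 297L),
  c(1L, 3L, 3L, 9L, 29L, 53L, 121L, 201L, 135L, 193L, 523L, 2943L),
  c(1L, 1L, 1L, 7L, 29L, 45L, 125L, 9L, 99L, 867L, 425L, 601L),
  c(1L, 3L, 1L, 9L, 13L, 15L, 67L, 181L, 109L, 293L, 1305L, 3079L),
  c(1L, 3L, 3L, 9L, 5L, 35L, 15L, 209L, 305L, 87L, 767L, 2795L),
  c(1L, 3L, 3L, 11L, 27L, 57L, 113L, 123L, 179L, 643L, 149L, 523L),
  c(1L, 1L, 3L, 15L, 11L, 17L, 67L, 223L, 63L, 657L, 335L, 3309L),
  c(1L, 1L, 1L, 9L, 25L, 29L, 109L, 159L, 39L, 513L, 571L, 1761L),
  c(1L, 1L, 3L, 1L, 5L, 63L, 75L, 19L, 455L, 601L, 123L, 691L),
  c(1L, 1L, 1L, 3L, 21L, 5L, 45L, 169L, 377L, 513L, 1951L, 2565L),
  c(1L, 1L, 3L, 11L, 3L, 33L, 119L, 69L, 253L, 907L, 805L, 1449L),
  c(1L, 1L, 5L, 13L, 31L, 15L, 17L, 7L, 499L, 61L, 687L, 1867L),
  c(1L, 3L, 7L, 11L, 17L, 33L, 73L, 77L, 299L, 243L, 641L, 2345L),
  c(1L, 1L, 7L, 11L, 9L, 35L, 31L, 235L, 359L, 647L, 379L, 1161L),
  c(1L, 3L, 3L, 15L, 31L, 25L, 5L, 67L, 33L, 45L, 437L, 4067L),
  c(1L, 1L, 3L, 11L, 7L, 17L, 37L, 87L, 333L, 253L, 1517L, 2921L),
  c(1L, 1L, 7L, 15L, 7L, 15L, 107L, 189L, 153L, 769L, 1521L, 3427L),
  c(1L, 3L, 5L, 13L, 5L, 61L, 113L, 37L, 293L, 393L, 113L, 43L),
  c(1L, 1L, 1L, 15L, 29L, 43L, 107L, 31L, 167L, 147L, 301L, 1021L),
  c(1L, 1L, 1L, 13L, 3L, 1L, 35L, 93L, 195L, 181L, 2027L, 1491L),
  c(1L, 3L, 3L, 3L, 13L, 33L, 77L, 199L, 153L, 221L, 1699L, 3671L),
  c(1L, 3L, 5L, 13L, 7L, 49L, 123L, 155L, 495L, 681L, 819L, 809L),
  c(1L, 3L, 5L, 15L, 27L, 61L, 117L, 189L, 183L, 887L, 617L, 4053L),
  c(1L, 1L, 1L, 7L, 31L, 59L, 125L, 235L, 389L, 369L, 447L, 1039L),
  c(1L, 3L, 5L, 1L, 5L, 39L, 115L, 89L, 249L, 377L, 431L, 3747L),
  c(1L, 1L, 1L, 5L, 7L, 47L, 59L, 157L, 77L, 445L, 699L, 3439L),
  c(1L, 1L, 3L, 5L, 11L, 21L, 19L, 75L, 11L, 599L, 1575L, 735L),
  c(1L, 3L, 5L, 3L, 19L, 13L, 41L, 69L, 199L, 143L, 1761L, 3215L),
  c(1L, 3L, 5L, 7L, 19L, 43L, 25L, 41L, 41L, 11L, 1647L, 2783L),
  c(1L, 3L, 1L, 9L, 19L, 45L, 111L, 97L, 405L, 399L, 457L, 3219L),
  c(1L, 1L, 3L, 1L, 23L, 15L, 65L, 121L, 59L, 985L, 829L, 2259L),
  c(1L, 1L, 3L, 7L, 17L, 13L, 107L, 229L, 75L, 551L, 1299L, 2363L),
  c(1L, 1L, 5L, 5L, 21L, 57L, 23L, 199L, 509L, 139L, 2007L, 3875L),
  c(1L, 3L, 1L, 11L, 19L, 53L, 15L, 229L, 215L, 741L, 695L, 823L),
  c(1L, 3L, 7L, 1L, 29L, 3L, 17L, 163L, 417L, 559L, 549L, 319L),
  c(1L, 3L, 1L, 13L, 17L, 9L, 47L, 133L, 365L, 7L, 1937L, 1071L),
  c(1L, 3L, 5L, 7L, 19L, 37L, 55L, 163L, 301L, 249L, 689L, 2327L),
  c(1L, 3L, 5L, 13L, 11L, 23L, 61L, 205L, 257L, 377L, 615L, 1457L),
  c(1L, 3L, 5L, 1L, 23L, 37L, 13L, 75L, 331L, 495L, 579L, 3367L),
  c(1L, 1L, 1L, 9L, 1L, 23L, 49L, 129L, 475L, 543L, 883L, 2531L),
  c(1L, 3L, 1L, 5L, 23L, 59L, 51L, 35L, 343L, 695L, 219L, 369L),
  c(1L, 3L, 3L, 1L, 27L, 17L, 63L, 97L, 71L, 507L, 1929L, 613L),
  c(1L, 1L, 5L, 1L, 21L, 31L, 11L, 109L, 247L, 409L, 1817L, 2173L),
  c(1L, 1L, 3L, 15L, 23L, 9L, 7L, 209L, 301L, 23L, 147L, 1691L),
  c(1L, 1L, 7L, 5L, 5L, 19L, 37L, 229L, 249L, 277L, 1115L, 2309L),
  c(1L, 1L, 1L, 5L, 5L, 63L, 5L, 249L, 285L, 431L, 343L, 2467L),
  c(1L, 1L, 1L, 11L, 7L, 45L, 35L, 75L, 505L, 537L, 29L, 2919L),
  c(1L, 3L, 5L, 15L, 11L, 39L, 15L, 63L, 263L, 9L, 199L, 445L),
  c(1L, 3L, 3L, 3L, 27L, 63L, 53L, 171L, 227L, 63L, 1049L, 827L),
  c(1L, 1L, 3L, 13L, 7L, 11L, 115L, 183L, 179L, 937L, 1785L, 381L),
  c(1L, 3L, 1L, 11L, 13L, 15L, 107L, 81L, 53L, 295L, 1785L, 3757L),
  c(1L, 3L, 3L, 13L, 11L, 5L, 109L, 243L, 3L, 505L, 323L, 1373L),
  c(1L, 3L, 3L, 11L, 21L, 51L, 17L, 177L, 381L, 937L, 1263L, 3889L),
  c(1L, 3L, 5L, 9L, 27L, 25L, 85L, 193L, 143L, 573L, 1189L, 2995L),
  c(1L, 3L, 5L, 11L, 13L, 9L, 81L, 21L, 159L, 953L, 91L, 1751L),
  c(1L, 1L, 3L, 3L, 27L, 61L, 11L, 253L, 391L, 333L, 1105L, 635L),
  c(1L, 3L, 3L, 15L, 9L, 57L, 95L, 81L, 419L, 735L, 251L, 1141L),
  c(1L, 1L, 5L, 9L, 31L, 39L, 59L, 13L, 319L, 807L, 1241L, 2433L),
  c(1L, 3L, 3L, 5L, 27L, 13L, 107L, 141L, 423L, 937L, 2027L, 3233L),
  c(1L, 3L, 3L, 9L, 9L, 25L, 125L, 23L, 443L, 835L, 1245L, 847L),
  c(1L, 1L, 7L, 15L, 17L, 17L, 83L, 107L, 411L, 285L, 847L, 1571L),
  c(1L, 1L, 3L, 13L, 29L, 61L, 37L, 81L, 349L, 727L, 1453L, 1957L),
  c(1L, 3L, 7L, 11L, 31L, 13L, 59L, 77L, 273L, 591L, 1265L, 1533L),
  c(1L, 1L, 7L, 7L, 13L, 17L, 25L, 25L, 187L, 329L, 347L, 1473L),
  c(1L, 3L, 7L, 7L, 5L, 51L, 37L, 99L, 221L, 153L, 503L, 2583L),
  c(1L, 3L, 1L, 13L, 19L, 27L, 11L, 69L, 181L, 479L, 1183L, 3229L),
  c(1L, 3L, 3L, 13L, 23L, 21L, 103L, 147L, 323L, 909L, 947L, 315L),
  c(1L, 3L, 1L, 3L, 23L, 1L, 31L, 59L, 93L, 513L, 45L, 2271L),
  c(1L, 3L, 5L, 1L, 7L, 43L, 109L, 59L, 231L, 41L, 1515L, 2385L),
  c(1L, 3L, 1L, 5L, 31L, 57L, 49L, 223L, 283L, 1013L, 11L, 701L),
  c(1L, 1L, 5L, 1L, 19L, 53L, 55L, 31L, 31L, 299L, 495L, 693L),
  c(1L, 3L, 3L, 9L, 5L, 33L, 77L, 253L, 427L, 791L, 731L, 1019L),
  c(1L, 3L, 7L, 11L, 1L, 9L, 119L, 203L, 53L, 877L, 1707L, 3499L),
  c(1L, 1L, 3L, 7L, 13L, 39L, 55L, 159L, 423L, 113L, 1653L, 3455L),
  c(1L, 1L, 3L, 5L, 21L, 47L, 51L, 59L, 55L, 411L, 931L, 251L),
  c(1L, 3L, 7L, 3L, 31L, 25L, 81L, 115L, 405L, 239L, 741L, 455L),
  c(1L, 1L, 5L, 1L, 31L, 3L, 101L, 83L, 479L, 491L, 1779L, 2225L),
  c(1L, 3L, 3L, 3L, 9L, 37L, 107L, 161L, 203L, 503L, 767L, 3435L),
  c(1L, 3L, 7L, 9L, 1L, 27L, 61L, 119L, 233L, 39L, 1375L, 4089L),
  c(1L, 1L, 5L, 9L, 1L, 31L, 45L, 51L, 369L, 587L, 383L, 2813L),
  c(1L, 3L, 7L, 5L, 31L, 7L, 49L, 119L, 487L, 591L, 1627L, 53L),
  c(1L, 1L, 7L, 1L, 9L, 47L, 1L, 223L, 369L, 711L, 1603L, 1917L),
  c(1L, 3L, 5L, 3L, 21L, 37L, 111L, 17L, 483L, 739L, 1193L, 2775L),
  c(1L, 3L, 3L, 7L, 17L, 11L, 51L, 117L, 455L, 191L, 1493L, 3821L),
  c(1L, 1L, 5L, 9L, 23L, 39L, 99L, 181L, 343L, 485L, 99L, 1931L),
  c(1L, 3L, 1L, 7L, 29L, 49L, 31L, 71L, 489L, 527L, 1763L, 2909L),
  c(1L, 1L, 5L, 11L, 5L, 5L, 73L, 189L, 321L, 57L, 1191L, 3685L),
  c(1L, 1L, 5L, 15L, 13L, 45L, 125L, 207L, 371L, 415L, 315L, 983L),
  c(1L, 3L, 3L, 5L, 25L, 59L, 33L, 31L, 239L, 919L, 1859L, 2709L),
  c(1L, 3L, 5L, 13L, 27L, 61L, 23L, 115L, 61L, 413L, 1275L, 3559L),
  c(1L, 3L, 7L, 15L, 5L, 59L, 101L, 81L, 47L, 967L, 809L, 3189L),
  c(1L, 1L, 5L, 11L, 31L, 15L, 39L, 25L, 173L, 505L, 809L, 2677L),
  c(1L, 1L, 5L, 9L, 19L, 13L, 95L, 89L, 511L, 127L, 1395L, 2935L),
  c(1L, 1L, 5L, 5L, 31L, 45L, 9L, 57L, 91L, 303L, 1295L, 3215L),
  c(1L, 3L, 3L, 3L, 19L, 15L, 113L, 187L, 217L, 489L, 1285L, 1803L),
  c(1L, 1L, 3L, 1L, 13L, 29L, 57L, 139L, 255L, 197L, 537L, 2183L),
  c(1L, 3L, 1L, 15L, 11L, 7L, 53L, 255L, 467L, 9L, 757L, 3167L),
  c(1L, 3L, 3L, 15L, 21L, 13L, 9L, 189L, 359L, 323L, 49L, 333L),
  c(1L, 3L, 7L, 11L, 7L, 37L, 21L, 119L, 401L, 157L, 1659L, 1069L),
  c(1L, 1L, 5L, 7L, 17L, 33L, 115L, 229L, 149L, 151L, 2027L, 279L),
  c(1L, 1L, 5L, 15L, 5L, 49L, 77L, 155L, 383L, 385L, 1985L, 945L),
  c(1L, 3L, 7L, 3L, 7L, 55L, 85L, 41L, 357L, 527L, 1715L, 1619L),
  c(1L, 1L, 3L, 1L, 21L, 45L, 115L, 21L, 199L, 967L, 1581L, 3807L),
  c(1L, 1L, 3L, 7L, 21L, 39L, 117L, 191L, 169L, 73L, 413L, 3417L),
  c(1L, 1L, 1L, 13L, 1L, 31L, 57L, 195L, 231L, 321L, 367L, 1027L),
  c(1L, 3L, 7L, 3L, 11L, 29L, 47L, 161L, 71L, 419L, 1721L, 437L),
  c(1L, 1L, 7L, 3L, 11L, 9L, 43L, 65L, 157L, 1L, 1851L, 823L),
  c(1L, 1L, 1L, 5L, 21L, 15L, 31L, 101L, 293L, 299L, 127L, 1321L),
  c(1L, 1L, 7L, 1L, 27L, 1L, 11L, 229L, 241L, 705L, 43L, 1475L),
  c(1L, 3L, 7L, 1L, 5L, 15L, 73L, 183L, 193L, 55L, 1345L, 49L),
  c(1L, 3L, 3L, 3L, 19L, 3L, 55L, 21L, 169L, 663L, 1675L, 137L),
  c(1L, 1L, 1L, 13L, 7L, 21L, 69L, 67L, 373L, 965L, 1273L, 2279L),
  c(1L, 1L, 7L, 7L, 21L, 23L, 17L, 43L, 341L, 845L, 465L, 3355L),
  c(1L, 3L, 5L, 5L, 25L, 5L, 81L, 101L, 233L, 139L, 359L, 2057L),
  c(1L, 1L, 3L, 11L, 15L, 39L, 55L, 3L, 471L, 765L, 1143L, 3941L),
  c(1L, 1L, 7L, 15L, 9L, 57L, 81L, 79L, 215L, 433L, 333L, 3855L),
  c(1L, 1L, 5L, 5L, 19L, 45L, 83L, 31L, 209L, 363L, 701L, 1303L),
  c(1L, 3L, 7L, 5L, 1L, 13L, 55L, 163L, 435L, 807L, 287L, 2031L),
  c(1L, 3L, 3L, 7L, 3L, 3L, 17L, 197L, 39L, 169L, 489L, 1769L),
  c(1L, 1L, 3L, 5L, 29L, 43L, 87L, 161L, 289L, 339L, 1233L, 2353L),
  c(1L, 3L, 3L, 9L, 21L, 9L, 77L, 1L, 453L, 167L, 1643L, 2227L),
  c(1L, 1L, 7L, 1L, 15L, 7L, 67L, 33L, 193L, 241L, 1031L, 2339L),
  c(1L, 3L, 1L, 11L, 1L, 63L, 45L, 65L, 265L, 661L, 849L, 1979L),
  c(1L, 3L, 1L, 13L, 19L, 49L, 3L, 11L, 159L, 213L, 659L, 2839L),
  c(1L, 3L, 5L, 11L, 9L, 29L, 27L, 227L, 253L, 449L, 1403L, 3427L),
  c(1L, 1L, 3L, 1L, 7L, 3L, 77L, 143L, 277L, 779L, 1499L, 475L),
  c(1L, 1L, 1L, 5L, 11L, 23L, 87L, 131L, 393L, 849L, 193L, 3189L),
  c(1L, 3L, 5L, 11L, 3L, 3L, 89L, 9L, 449L, 243L, 1501L, 1739L),
  c(1L, 3L, 1L, 9L, 29L, 29L, 113L, 15L, 65L, 611L, 135L, 3687L),
  c(1L, 1L, 1L, 9L, 21L, 19L, 39L, 151L, 395L, 501L, 1339L, 959L, 2725L),
  c(1L, 3L, 7L, 1L, 7L, 35L, 45L, 33L, 119L, 225L, 1631L, 1695L, 1459L),
  c(1L, 1L, 1L, 3L, 25L, 55L, 37L, 79L, 167L, 907L, 1075L, 271L, 4059L),
  c(1L, 3L, 5L, 13L, 5L, 13L, 53L, 165L, 437L, 67L, 1705L, 3177L, 8095L),
  c(1L, 3L, 3L, 13L, 27L, 57L, 95L, 55L, 443L, 245L, 1945L, 1725L, 1929L),
  c(1L, 3L, 1L, 9L, 5L, 33L, 109L, 35L, 99L, 827L, 341L, 2401L, 2411L),
  c(1L, 1L, 5L, 9L, 7L, 33L, 43L, 39L, 87L, 799L, 635L, 3481L, 7159L),
  c(1L, 3L, 1L, 1L, 31L, 15L, 45L, 27L, 337L, 113L, 987L, 2065L, 2529L),
  c(1L, 1L, 5L, 9L, 5L, 15L, 105L, 123L, 479L, 289L, 1609L, 2177L, 4629L),
  c(1L, 3L, 5L, 11L, 31L, 47L, 97L, 87L, 385L, 195L, 1041L, 651L, 3271L),
  c(1L, 1L, 3L, 7L, 17L, 3L, 101L, 55L, 87L, 629L, 1687L, 1387L, 2745L),
  c(1L, 3L, 5L, 5L, 7L, 21L, 9L, 237L, 313L, 549L, 1107L, 117L, 6183L),
  c(1L, 1L, 3L, 9L, 9L, 5L, 55L, 201L, 487L, 851L, 1103L, 2993L, 4055L),
  c(1L, 1L, 5L, 9L, 31L, 19L, 59L, 7L, 363L, 381L, 1167L, 2057L, 5715L),
  c(1L, 3L, 3L, 15L, 23L, 63L, 19L, 227L, 387L, 827L, 487L, 1049L, 7471L),
  c(1L, 3L, 1L, 5L, 23L, 25L, 61L, 245L, 363L, 863L, 963L, 3583L, 6475L),
  c(1L, 1L, 5L, 1L, 5L, 27L, 81L, 85L, 275L, 49L, 235L, 3291L, 1195L),
  c(1L, 1L, 5L, 7L, 23L, 53L, 85L, 107L, 511L, 779L, 1265L, 1093L, 7859L),
  c(1L, 3L, 3L, 1L, 9L, 21L, 75L, 219L, 59L, 485L, 1739L, 3845L, 1109L),
  c(1L, 3L, 5L, 1L, 13L, 41L, 19L, 143L, 293L, 391L, 2023L, 1791L, 4399L),
  c(1L, 3L, 7L, 15L, 21L, 13L, 21L, 195L, 215L, 413L, 523L, 2099L, 2341L),
  c(1L, 1L, 1L, 3L, 29L, 51L, 47L, 57L, 135L, 575L, 943L, 1673L, 541L),
  c(1L, 3L, 5L, 1L, 9L, 13L, 113L, 175L, 447L, 115L, 657L, 4077L, 5973L),
  c(1L, 1L, 1L, 11L, 17L, 41L, 37L, 95L, 297L, 579L, 911L, 2207L, 2387L),
  c(1L, 3L, 5L, 3L, 23L, 11L, 23L, 231L, 93L, 667L, 711L, 1563L, 7961L),
  c(1L, 1L, 7L, 3L, 17L, 59L, 13L, 181L, 141L, 991L, 1817L, 457L, 1711L),
  c(1L, 3L, 3L, 5L, 31L, 59L, 81L, 205L, 245L, 537L, 1049L, 997L, 1815L),
  c(1L, 3L, 7L, 5L, 17L, 13L, 9L, 79L, 17L, 185L, 5L, 2211L, 6263L),
  c(1L, 3L, 7L, 13L, 7L, 53L, 61L, 145L, 13L, 285L, 1203L, 947L, 2933L),
  c(1L, 1L, 7L, 3L, 31L, 19L, 69L, 217L, 47L, 441L, 1893L, 673L, 4451L),
  c(1L, 1L, 1L, 1L, 25L, 9L, 23L, 225L, 385L, 629L, 603L, 3747L, 4241L)
)
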