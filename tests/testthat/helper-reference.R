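# Published reference screen: the WHO-pharmacovigilance-database
# disproportionality analysis of the six immune checkpoint inhibitors whose
# printed contingency cells and IC results this package is validated
# against. Columns `ic`, `lo`, `hi` hold the printed values; `signal` the
# printed verdict.
#
# Three typographical defects in the printed results are annotated rather
# than asserted:
#  - atezolizumab:fractures prints IC -0.03, but the printed interval
#    [-0.37, 0.43] is symmetric about +0.03: a sign misprint
#    (`ic_sign_misprint`); the computed value is +0.03.
#  - atezolizumab:hyperthyroidism prints upper bound 6.49, inconsistent with
#    a symmetric E +/- 2*sqrt(V) interval around 4.47 (`hi_misprint`).
#  - nivolumab:fractures prints lower bound -3.08, likewise inconsistent
#    around -0.09 (`lo_misprint`).
reference_screen <- function() {
  tab <- read.csv(text = trimws("
term,drug,n11,n10,n01,n00,ic,lo,hi,signal
osteoporosis,all_icis,44,108468,37009,25874084,-1.79,-2.22,-1.36,NO
osteoporosis,nivolumab,24,47579,37029,25934973,-1.46,-2.04,-0.89,NO
osteoporosis,pembrolizumab,14,37723,37039,25944829,-1.87,-2.61,-1.12,NO
osteoporosis,atezolizumab,3,12472,37050,25970080,-2.23,-3.67,-0.79,NO
osteoporosis,durvalumab,1,4611,37052,25977941,-1.92,-3.96,0.12,NO
osteoporosis,ipilimumab,6,19912,37047,25962640,-2.07,-3.16,-0.98,NO
osteoporosis,tremelimumab,0,478,37053,25982074,NA,NA,NA,NA
hyperthyroidism,all_icis,1532,106980,12808,25898285,4.66,4.58,4.73,YES
hyperthyroidism,nivolumab,796,46807,13544,25958458,4.87,4.77,4.98,YES
hyperthyroidism,pembrolizumab,436,37301,13904,25967964,4.33,4.18,4.47,YES
hyperthyroidism,atezolizumab,174,12301,14166,25992964,4.47,4.25,6.49,YES
hyperthyroidism,durvalumab,88,4524,14252,26000741,4.65,4.34,4.96,YES
hyperthyroidism,ipilimumab,354,19564,13986,25985701,4.89,4.73,5.05,YES
hyperthyroidism,tremelimumab,2,476,14338,26004789,1.25,-0.42,2.92,NO
fractures,all_icis,375,108137,103979,25807114,-0.21,-0.36,-0.06,NO
fractures,nivolumab,179,47424,104175,25867827,-0.09,-3.08,0.12,NO
fractures,pembrolizumab,114,37623,104240,25877628,-0.41,-0.68,-0.14,NO
fractures,atezolizumab,51,12424,104303,25902827,-0.03,-0.37,0.43,NO
fractures,durvalumab,14,4598,104340,25910653,-0.38,-1.12,0.37,NO
fractures,ipilimumab,79,19839,104275,25895412,-0.02,-0.34,0.31,NO
fractures,tremelimumab,1,477,104353,25914774,-0.55,-2.59,1.50,NO
"), stringsAsFactors = FALSE)
  tab$ic_sign_misprint <- tab$term == "fractures" & tab$drug == "atezolizumab"
  tab$hi_misprint <- tab$term == "hyperthyroidism" & tab$drug == "atezolizumab"
  tab$lo_misprint <- tab$term == "fractures" & tab$drug == "nivolumab"
  tab
}

reference_table <- function(row) {
  contingency_table(row$n11, row$n10, row$n01, row$n00,
                    drug_set = row$drug, term_set = row$term)
}
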