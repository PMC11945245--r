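# Fixture set definitions shipped with the package.
# Drug sets use real WHODrug substance ids; preferred-term codes are
# documented placeholders drawn from the reserved 90000xxx range (real
# MedDRA codes are licensed and must be supplied by the user). Cardinalities
# match the published definitions: 11 osteoporosis PTs, 19 hyperthyroidism
# PTs, 78 fracture PTs across six high-level-term blocks (7/4/10/4/29/24).
drug_sets:
  - name: nivolumab
    substance_ids: [27193]
  - name: pembrolizumab
    substance_ids: [28886]
  - name: atezolizumab
    substance_ids: [32021]
  - name: durvalumab
    substance_ids: [31669]
  - name: ipilimumab
    substance_ids: [17640]
  - name: tremelimumab
    substance_ids: [18514, 38501]
  - name: all_icis
    substance_ids: [17640, 18514, 27193, 28886, 31669, 32021, 38501]
term_sets:
  - name: osteoporosis
    grouping_source: "SMQ 20000178"
    pt_codes: [90000101, 90000102, 90000103, 90000104, 90000105, 90000106, 90000107, 90000108, 90000109, 90000110, 90000111]
  - name: hyperthyroidism
    grouping_source: "SMQ 20000161"
    pt_codes: [90000201, 90000202, 90000203, 90000204, 90000205, 90000206, 90000207, 90000208, 90000209, 90000210, 90000211, 90000212, 90000213, 90000214, 90000215, 90000216, 90000217, 90000218, 90000219]
  - name: fractures
    grouping_source: "HLGT 10017322"
    pt_codes: [
      # skull and face (7 PTs)
      90000301, 90000302, 90000303, 90000304, 90000305, 90000306, 90000307,
      # thoracic cage non-spinal (4 PTs)
      90000308, 90000309, 90000310, 90000311,
      # spinal column (10 PTs)
      90000312, 90000313, 90000314, 90000315, 90000316, 90000317, 90000318, 90000319, 90000320, 90000321,
      # pelvic (4 PTs)
      90000322, 90000323, 90000324, 90000325,
      # limb (29 PTs)
      90000326, 90000327, 90000328, 90000329, 90000330, 90000331, 90000332, 90000333, 90000334, 90000335,
      90000336, 90000337, 90000338, 90000339, 90000340, 90000341, 90000342, 90000343, 90000344, 90000345,
      90000346, 90000347, 90000348, 90000349, 90000350, 90000351, 90000352, 90000353, 90000354,
      # fractures nec (24 PTs)
      90000355, 90000356, 90000357, 90000358, 90000359, 90000360, 90000361, 90000362, 90000363, 90000364,
      90000365, 90000366, 90000367, 90000368, 90000369, 90000370, 90000371, 90000372, 90000373, 90000374,
      90000375, 90000376, 90000377, 90000378
    ]
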