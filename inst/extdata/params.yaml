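# Default model parameters: per-farm cost-benefit analysis of renovating
# farm dams on beef cattle farms, real 2019 AUD throughout.
discount:
  rate: 0.07            # real social discount rate, per annum
  horizon_years: 50     # life of a well-maintained renovated dam

benefits:
  weight_gain_fraction: 0.11   # deterministic additional annual weight gain
  base_sale_weight_kg: 400     # feeder steer sale weight, top of 330-400 range
  fertiliser_per_100head_year: 1047  # AUD/yr avoided fertiliser per 100 head
  bogging_saving_per_year: 0   # conservatively zero
  mastitis_saving_per_year: 0  # conservatively zero

desilting:
  cost_per_event: 3000
  poor_years: [10, 20, 30, 40, 50]      # poor-condition dam, 50-year cycle
  poor_cycle_years: 50
  renovated_years: [20, 40, 60]         # renovated dam, 60-year cycle
  renovated_cycle_years: 60

dams:
  ha_per_dam: 40        # one renovated dam per 40 ha of pasture

costs:
  fence_materials: 3285
  fence_labour: 2190
  watering_gravel: 560
  watering_spreading: 100
  watering_extra_fence: 1300
  watering_submersible: 1088
  vegetation_trees_shrubs: 107.80
  vegetation_grasses: 28.50
  vegetation_labour: 238.00
  fence_maint:
    amount: 350         # one day of labour (7 h at $50/h)
    every_years: 10
  fence_maint_cycle_years: 50
  watering_maint:
    - amount: 500       # gravel + delivery ($300) and machinery + operator ($200)
      every_years: 10
    - amount: 400       # submersible mesh ($300 material + 2 h labour)
      every_years: 15
  watering_maint_cycle_years: 60   # common cycle of the 10- and 15-year events

regions:
  NSW:
    price_per_kg: 3.19  # mean 2015-2019 feeder steer liveweight price
  Victoria:
    price_per_kg: 3.03

simulation:
  n_replicates: 100000
  gain_lower: 0.00      # uniform weight-gain bounds across the three studies
  gain_upper: 0.23
  price_sigma: 0.14     # sd of zero-mean normal log real returns
  price_init_vic: 3.03  # starting Victorian price, AUD/kg
  nsw_price_offset: 0.16  # NSW price = Victorian price + offset
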