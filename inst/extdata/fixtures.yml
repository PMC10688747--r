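seed: 1.0
files:
  fixture_pop_climate.csv:
    scenario: northern-like (climate-driven)
    seed: 1.0
    variant: pop_climate
  fixture_pop_warfare.csv:
    scenario: southern-like (warfare-driven)
    seed: 1.0
    variant: pop_warfare
  fixture_pop_climate_warfare.csv:
    scenario: boom-bust (productivity coupling)
    seed: 1.0
    variant: pop_climate_warfare
  fixture_war_basic.csv:
    scenario: boom-bust (productivity coupling)
    seed: 1.0
    variant: war_basic
  fixture_war_additive_climate.csv:
    scenario: northern-like (climate-driven)
    seed: 1.0
    variant: war_additive_climate
  fixture_war_pressure.csv:
    scenario: southern-like (warfare-driven)
    seed: 1.0
    variant: war_pressure
  fixture_sdata_synthetic.csv:
    scenario: northern-like (climate-driven)
    seed: 1.0
    note: synthetic, nine-column exchange layout
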