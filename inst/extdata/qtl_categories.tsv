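traitType	category
Production	Production
Production_Trait	Production
Meat_and_Carcass	Meat and Carcass
Meat and Carcass	Meat and Carcass
Health	Health
Milk	Milk
Exterior	Exterior
Reproduction	Reproduction
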