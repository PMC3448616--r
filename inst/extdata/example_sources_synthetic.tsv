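molecule_id	source_name	genus	antidiabetic_flag	references
HIT_001	Erythrina variegata	Erythrina	reported	doi:10.0000/synthetic-001
HIT_001	Erythrina poeppigiana	Erythrina	none	doi:10.0000/synthetic-002
HIT_002	Tecoma stans	Tecoma	reported	doi:10.0000/synthetic-003
HIT_003	Scoparia dulcis	Scoparia	reported	doi:10.0000/synthetic-004
HIT_004	Ephedra distachya	Ephedra	reported	doi:10.0000/synthetic-005
HIT_004	Ephedra equisetina	Ephedra	none	doi:10.0000/synthetic-006
HIT_005	Rauwolfia serpentina	Rauwolfia	reported	doi:10.0000/synthetic-007
HIT_006	Solanum nudum	Solanum	none	doi:10.0000/synthetic-008
HIT_006	Solanum nigrum	Solanum	reported	doi:10.0000/synthetic-009
HIT_007	Stephania cepharantha	Stephania	genus_related	doi:10.0000/synthetic-010
HIT_008	Vitis vinifera	Vitis	reported	doi:10.0000/synthetic-011
HIT_009	Calendula officinalis	Calendula	none	doi:10.0000/synthetic-012
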