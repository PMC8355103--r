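sample_id	status	age	sex	family_history	bmi	pack_years	time_to_dx_years
S0001	control	66.495758911455	M	0	27.4994926948678	4.78593760350486	NA
S0002	control	58.1321083555982	F	0	29.6497693758799	0	NA
S0003	control	70.7950198597492	M	1	26.5063564409056	0	NA
S0004	case	68.8315528283185	M	1	32.4498387524441	28.5021194128798	1.46755437506363
S0005	control	53.9114160474846	F	0	27.0243239398608	13.2573394642429	NA
S0006	case	74.0487543017296	F	0	27.207450808602	0	7.14304759027436
S0007	control	69.7923455458414	M	0	31.4968823414741	0	NA
S0008	case	56.8249883856836	M	0	24.6285887282158	0	6.24408407881856
S0009	case	61.0947030973281	M	1	23.214287286901	0	5.5871923295781
S0010	case	66.9534539372242	M	0	25.4596289487858	19.3628932760792	10.8308630981483
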