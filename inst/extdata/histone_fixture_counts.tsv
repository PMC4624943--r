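sample_id	group	gene_id	count
case_1	case	u1	3
case_1	case	u2	3
case_1	case	u3	3
case_1	case	canH	12
case_1	case	varH	0
case_2	case	u1	6
case_2	case	u2	6
case_2	case	u3	6
case_2	case	canH	25
case_2	case	varH	2
control_1	control	u1	2
control_1	control	u2	2
control_1	control	u3	2
control_1	control	canH	4
control_1	control	varH	3
control_2	control	u1	4
control_2	control	u2	4
control_2	control	u3	4
control_2	control	canH	8
control_2	control	varH	3
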