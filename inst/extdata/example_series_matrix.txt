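!Series_title	"Synthetic example series for format testing"
!Series_geo_accession	"GSE00000"
!Sample_title	"tumor_1"	"tumor_2"	"control_1"
!Sample_geo_accession	"GSM000001"	"GSM000002"	"GSM000003"
!Sample_source_name_ch1	"meningioma"	"meningioma"	"arachnoid"
!series_matrix_table_begin
"ID_REF"	"GSM000001"	"GSM000002"	"GSM000003"
"P0001"	7.25	7.31	6.98
"P0002"	10.02	9.87	10.11
"P0003"	5.5	5.61	5.4
"P0004"	8.125	8.25	8.5
"P0005"	11.75	11.5	11.9
!series_matrix_table_end
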