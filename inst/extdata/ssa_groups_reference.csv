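country,group,note
Angola,1,
Burkina Faso,1,
Burundi,1,
Central African Republic,1,
Chad,1,
Democratic Republic of the Congo,1,
Ethiopia,1,
Guinea-Bissau,1,
Liberia,1,
Mali,1,
Niger,1,
Sierra Leone,1,
Somalia,1,
Benin,2,
Cameroon,2,
Comoros,2,
Congo,2,
Cote d'Ivoire,2,
Ghana,2,
Guinea,2,
Madagascar,2,
Malawi,2,
Mauritania,2,
Mozambique,2,
Nigeria,2,
Rwanda,2,
Sudan,2,
Tanzania,2,
Togo,2,
Uganda,2,
Zambia,2,
Zimbabwe,2,also listed under group 3; conflict kept unresolved
Botswana,3,
Equatorial Guinea,3,
Eritrea,3,
Gambia,3,
Kenya,3,
Lesotho,3,
Namibia,3,
Senegal,3,
Swaziland,3,
Zimbabwe,3,also listed under group 2; conflict kept unresolved
Cape Verde,4,
Gabon,4,
Mauritius,4,
Seychelles,4,
South Africa,4,
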