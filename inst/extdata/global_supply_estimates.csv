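country,mean_total_2004_2013,sd_total_2004_2013,mean_less_ohd_2004_2013,sd_less_ohd_2004_2013,mean_total_2014_2017,sd_total_2014_2017,mean_less_ohd_2014_2017,sd_less_ohd_2014_2017
Afghanistan,0.5,0.0,0.4,0.0,0.5,0.0,0.4,0.0
Albania,2.9,0.3,2.6,0.2,3.5,0.1,3.1,0.1
Algeria,1.8,0.1,1.6,0.1,1.9,0.0,1.6,0.0
Angola,1.9,0.3,1.7,0.3,3.0,0.6,2.8,0.5
Antigua and Barbuda,4.1,0.4,3.8,0.3,4.0,0.1,3.7,0.1
Argentina,3.2,0.3,2.8,0.2,3.7,0.0,3.2,0.0
Armenia,2.4,0.5,2.1,0.4,3.2,0.0,2.8,0.0
Australia,4.3,0.3,3.9,0.2,4.8,0.0,4.3,0.0
Austria,5.0,0.2,4.5,0.1,4.9,0.1,4.3,0.0
Azerbaijan,1.7,0.3,1.5,0.2,2.0,0.1,1.7,0.1
Bahamas,4.7,0.2,4.3,0.2,4.2,0.1,3.8,0.1
Bangladesh,2.5,0.3,2.3,0.2,3.4,0.1,3.1,0.1
Barbados,5.7,0.5,5.2,0.4,6.2,0.1,5.7,0.1
Belarus,5.2,0.4,4.6,0.4,5.0,0.1,4.4,0.1
Belgium,5.9,1.5,5.4,1.4,5.0,0.1,4.4,0.1
Belize,2.7,0.3,2.4,0.3,2.1,0.1,1.9,0.0
Benin,1.1,0.1,1.0,0.1,1.9,0.2,1.7,0.1
Bermuda,4.5,0.6,4.0,0.6,,,,
Bolivia (Plurinational State of),1.7,0.1,1.5,0.1,1.9,0.1,1.7,0.0
Bosnia and Herzegovina,1.9,0.1,1.8,0.1,2.1,0.0,1.9,0.0
Botswana,1.3,0.1,1.2,0.1,1.5,0.1,1.4,0.1
Brazil,3.0,0.4,2.6,0.3,3.3,0.0,2.9,0.0
Brunei Darussalam,3.8,0.3,3.4,0.3,,,,
Bulgaria,3.0,0.1,2.6,0.1,3.0,0.0,2.7,0.0
Burkina Faso,1.1,0.1,0.9,0.1,1.3,0.0,1.2,0.0
Cabo Verde,2.7,0.4,2.5,0.4,2.1,0.0,1.9,0.0
Cambodia,4.8,0.8,4.3,0.7,5.5,0.1,5.0,0.0
Cameroon,2.3,0.2,2.1,0.2,2.3,0.3,2.1,0.3
Canada,4.5,0.1,4.0,0.1,4.8,0.0,4.3,0.0
Central African Republic,1.8,0.1,1.6,0.1,1.8,0.0,1.6,0.0
Chad,1.0,0.1,0.9,0.1,1.7,0.0,1.6,0.0
Chile,3.3,0.2,3.0,0.2,3.4,0.1,2.9,0.1
China,4.9,0.4,4.3,0.4,6.0,0.0,5.2,0.0
"China, Hong Kong SAR",5.6,0.6,5.0,0.6,7.4,0.2,6.5,0.2
"China, Macao SAR",5.1,0.5,4.5,0.4,6.0,0.2,5.2,0.2
"China, mainland",4.9,0.4,4.3,0.4,6.0,0.0,5.2,0.0
"China, Taiwan Province of",4.3,0.2,3.8,0.2,4.1,0.1,3.6,0.1
Cote d'Ivoire,1.8,0.3,1.7,0.3,2.7,0.0,2.5,0.0
Colombia,2.7,0.2,2.3,0.2,3.2,0.0,2.8,0.0
Congo,2.9,0.4,2.7,0.4,3.3,0.1,3.0,0.1
Costa Rica,3.2,0.4,2.8,0.4,4.4,0.3,3.9,0.3
Croatia,4.5,0.3,4.0,0.3,4.5,0.2,4.0,0.2
Cuba,2.3,0.3,2.0,0.2,2.5,0.0,2.2,0.0
Cyprus,3.9,0.2,3.5,0.2,3.7,0.0,3.3,0.0
Czechia,4.3,0.2,3.8,0.2,3.7,0.0,3.3,0.0
DPR of Korea,0.7,0.1,0.6,0.0,0.7,0.0,0.6,0.0
Denmark,6.1,0.4,5.4,0.4,5.5,0.1,4.9,0.1
Djibouti,0.9,0.1,0.8,0.1,1.9,2.0,1.8,1.8
Dominica,4.7,0.6,4.3,0.6,5.4,0.2,5.0,0.2
Dominican Republic,2.2,0.2,2.0,0.2,2.7,0.1,2.4,0.1
Ecuador,2.4,0.3,2.2,0.2,2.7,0.2,2.4,0.2
Egypt,3.0,0.6,2.7,0.5,3.9,0.1,3.5,0.1
El Salvador,2.2,0.2,1.9,0.2,2.5,0.1,2.2,0.1
Estonia,3.8,0.3,3.4,0.2,3.9,0.1,3.5,0.1
Eswatini,1.1,0.7,1.0,0.6,0.9,0.1,0.8,0.1
Ethiopia,0.3,0.0,0.3,0.0,0.3,0.0,0.3,0.0
Fiji,5.7,0.4,5.2,0.3,4.4,0.0,4.1,0.0
Finland,7.8,0.3,7.1,0.3,7.9,0.2,7.2,0.2
France,5.7,0.2,5.1,0.1,5.4,0.1,4.9,0.1
French Polynesia,7.1,0.1,6.5,0.1,7.0,0.2,6.3,0.2
Gabon,4.8,0.3,4.5,0.3,4.8,0.3,4.4,0.2
Gambia,3.5,0.4,3.2,0.4,3.4,0.5,3.2,0.5
Georgia,2.5,0.3,2.2,0.2,2.4,0.1,2.1,0.1
Germany,4.6,0.1,4.1,0.1,4.5,0.1,4.0,0.1
Ghana,4.6,0.4,4.2,0.4,4.2,0.2,3.8,0.2
Greece,3.9,0.2,3.5,0.2,3.7,0.1,3.3,0.1
Grenada,5.5,0.3,5.0,0.3,4.8,0.2,4.3,0.2
Guatemala,2.1,0.1,1.7,0.1,2.0,0.0,1.7,0.0
Guinea,1.2,0.3,1.1,0.2,1.9,0.1,1.7,0.0
Guinea-Bissau,0.5,0.0,0.4,0.0,0.8,0.6,0.7,0.5
Guyana,1.6,0.2,1.5,0.1,1.5,0.5,1.4,0.5
Haiti,0.8,0.1,0.7,0.1,0.9,0.1,0.8,0.1
Honduras,1.7,0.2,1.5,0.2,1.3,0.0,1.2,0.0
Hungary,3.9,0.3,3.4,0.2,3.7,0.2,3.3,0.1
Iceland,14.2,0.7,13.3,0.6,14.7,0.0,13.7,0.0
India,1.1,0.1,1.0,0.1,1.4,0.1,1.3,0.1
Indonesia,3.6,0.5,3.3,0.4,5.2,0.5,4.7,0.4
Iran (Islamic Republic of),2.3,0.2,2.1,0.1,2.9,0.1,2.6,0.1
Iraq,1.0,0.4,0.9,0.3,1.3,0.2,1.1,0.2
Ireland,4.6,0.2,4.1,0.2,5.3,0.3,4.8,0.3
Israel,4.5,0.5,4.1,0.5,5.6,0.2,5.1,0.2
Italy,4.7,0.1,4.1,0.0,4.6,0.1,4.1,0.1
Jamaica,3.1,0.2,2.9,0.2,2.8,0.1,2.6,0.1
Japan,6.2,0.2,5.5,0.2,6.0,0.0,5.3,0.0
Jordan,1.7,0.2,1.6,0.1,1.6,0.1,1.5,0.0
Kazakhstan,3.0,0.3,2.7,0.3,3.0,0.0,2.7,0.0
Kenya,1.2,0.1,1.1,0.1,1.1,0.0,1.0,0.0
Kiribati,8.3,2.0,7.6,1.8,8.8,4.3,8.1,3.9
Kuwait,4.0,0.3,3.6,0.3,3.4,0.1,3.0,0.1
Kyrgyzstan,1.7,0.1,1.6,0.1,2.0,0.9,1.8,0.7
Lao PDR,3.1,0.3,2.8,0.3,4.4,0.1,4.0,0.1
Latvia,5.7,0.9,5.1,0.8,5.4,0.1,4.8,0.1
Lebanon,2.1,2.2,1.9,2.0,1.6,0.1,1.4,0.1
Lesotho,0.5,0.0,0.4,0.0,0.7,0.1,0.7,0.1
Liberia,0.7,0.1,0.7,0.1,1.1,0.1,1.0,0.1
Lithuania,9.1,0.8,8.3,0.7,8.7,0.2,7.9,0.2
Luxembourg,5.0,0.5,4.5,0.4,5.3,0.1,4.7,0.1
Madagascar,0.9,0.1,0.8,0.1,0.7,0.0,0.6,0.0
Malawi,1.1,0.2,1.0,0.2,1.7,0.2,1.6,0.2
Malaysia,6.5,0.5,5.9,0.5,6.7,0.2,6.0,0.2
Maldives,19.4,6.7,17.8,6.2,21.9,3.9,20.1,3.6
Mali,1.8,0.2,1.7,0.2,1.5,0.1,1.4,0.1
Malta,6.1,0.3,5.4,0.2,5.8,0.1,5.2,0.1
Mauritania,2.1,0.1,2.0,0.1,2.0,0.1,1.9,0.1
Mauritius,3.2,0.3,2.9,0.3,3.5,0.0,3.1,0.0
Mexico,3.7,0.2,3.2,0.1,4.6,0.1,4.0,0.1
Mongolia,1.5,0.1,1.4,0.1,1.9,0.1,1.8,0.1
Montenegro,3.7,0.5,3.4,0.4,4.5,0.2,4.0,0.2
Morocco,2.8,0.6,2.5,0.6,4.0,0.3,3.6,0.3
Mozambique,0.5,0.2,0.5,0.1,1.0,0.0,0.9,0.0
Myanmar,4.1,1.1,3.7,1.0,6.4,0.1,5.8,0.1
Namibia,2.0,0.3,1.8,0.3,2.0,0.0,1.9,0.0
Nepal,0.7,0.0,0.6,0.0,0.9,0.0,0.8,0.0
Netherlands,5.8,0.4,5.2,0.4,5.0,0.0,4.5,0.0
Netherlands Antilles (former),4.0,0.2,3.7,0.2,,,,
New Caledonia,4.8,0.2,4.4,0.2,4.4,0.1,3.9,0.1
New Zealand,5.2,0.4,4.7,0.4,4.3,0.1,3.9,0.1
Nicaragua,1.5,0.2,1.3,0.1,1.9,0.1,1.7,0.1
Niger,0.9,0.1,0.8,0.1,0.7,0.1,0.6,0.0
Nigeria,2.0,0.3,1.8,0.3,1.6,0.2,1.5,0.2
North Macedonia,2.4,0.1,2.2,0.1,2.2,0.1,2.0,0.0
Norway,5.1,0.3,4.6,0.3,5.5,0.2,5.0,0.2
Oman,3.6,0.5,3.3,0.4,3.7,0.1,3.4,0.1
Pakistan,1.3,0.1,1.2,0.1,1.3,0.0,1.2,0.0
Panama,2.9,0.2,2.6,0.2,3.2,0.0,2.9,0.0
Paraguay,3.3,0.1,2.8,0.0,3.0,0.4,2.6,0.3
Peru,3.6,0.3,3.3,0.3,4.2,0.2,3.8,0.2
Philippines,5.4,0.3,4.9,0.3,4.8,0.1,4.3,0.1
Poland,4.1,0.2,3.7,0.2,3.9,0.0,3.5,0.0
Portugal,5.5,0.4,4.9,0.4,5.3,0.1,4.9,0.1
Republic of Korea,5.3,0.2,4.7,0.1,5.2,0.1,4.7,0.1
Republic of Moldova,3.4,0.2,3.0,0.2,3.0,0.1,2.7,0.1
Romania,3.6,0.2,3.2,0.1,3.8,0.0,3.4,0.0
Russian Federation,4.9,0.4,4.4,0.4,4.9,0.2,4.3,0.1
Rwanda,0.3,0.1,0.3,0.1,0.6,0.0,0.6,0.0
Saint Kitts and Nevis,3.2,0.2,3.0,0.2,2.7,0.0,2.5,0.0
Saint Lucia,4.6,0.5,4.2,0.5,4.8,0.1,4.4,0.1
Saint Vincent and the Grenadines,2.9,0.1,2.6,0.1,2.7,0.0,2.5,0.0
Samoa,8.2,0.5,7.5,0.5,8.2,0.2,7.5,0.2
Sao Tome and Principe,3.6,0.1,3.3,0.1,3.8,0.2,3.5,0.2
Saudi Arabia,2.4,0.4,2.2,0.4,2.8,0.0,2.6,0.0
Senegal,3.9,0.4,3.6,0.4,2.7,0.1,2.5,0.1
Serbia,2.7,0.3,2.4,0.2,3.1,0.1,2.7,0.1
Serbia and Montenegro,3.1,0.0,2.7,0.0,,,,
Sierra Leone,4.1,0.6,3.8,0.6,3.6,0.1,3.3,0.1
Slovakia,3.5,0.2,3.0,0.1,3.4,0.2,3.0,0.2
Slovenia,3.9,0.2,3.5,0.2,3.7,0.1,3.3,0.1
Solomon Islands,2.8,0.3,2.5,0.2,4.2,0.4,3.8,0.4
South Africa,2.3,0.1,2.0,0.1,2.2,0.1,2.0,0.1
Spain,5.8,0.2,5.2,0.2,5.8,0.2,5.1,0.2
Sri Lanka,3.9,0.4,3.5,0.4,4.9,0.0,4.5,0.0
Sudan,1.0,0.0,1.0,0.0,0.9,0.0,0.8,0.0
Sudan (former),1.2,0.0,1.1,0.0,,,,
Suriname,1.9,0.4,1.7,0.4,3.9,0.7,3.6,0.6
Sweden,6.0,0.2,5.4,0.2,5.9,0.1,5.3,0.1
Switzerland,4.5,0.1,4.0,0.1,4.5,0.1,4.0,0.0
Tajikistan,0.5,0.1,0.5,0.1,0.6,0.0,0.5,0.0
Thailand,4.6,0.2,4.1,0.1,4.4,0.4,3.9,0.4
Timor-Leste,0.7,0.2,0.6,0.2,1.0,0.1,0.9,0.1
Togo,1.1,0.2,1.0,0.2,1.6,0.1,1.4,0.1
Trinidad and Tobago,2.9,0.2,2.7,0.2,3.0,0.1,2.7,0.1
Tunisia,2.9,0.1,2.6,0.1,2.8,0.1,2.5,0.1
Turkey,2.5,0.1,2.3,0.1,2.3,0.0,2.1,0.0
Turkmenistan,2.3,0.1,2.1,0.1,2.7,0.1,2.1,0.0
Uganda,2.2,0.2,2.0,0.2,2.2,0.2,2.0,0.2
Ukraine,4.7,0.4,4.1,0.4,3.8,0.3,3.3,0.2
United Arab Emirates,3.1,0.4,2.9,0.4,3.9,0.2,3.5,0.1
United Kingdom,4.2,0.1,3.7,0.1,3.9,0.0,3.5,0.0
United Republic of Tanzania,1.2,0.1,1.1,0.1,1.2,0.1,1.1,0.1
United States of America,5.0,0.1,4.4,0.0,5.1,0.0,4.5,0.0
Uruguay,3.1,0.4,2.7,0.4,3.3,0.2,2.9,0.2
Uzbekistan,1.3,0.1,1.1,0.1,2.0,0.1,1.8,0.1
Vanuatu,4.6,0.5,4.2,0.5,3.3,0.1,3.0,0.1
Venezuela (Bolivarian Republic of),3.0,0.2,2.7,0.2,2.6,0.2,2.4,0.2
Viet Nam,3.2,0.5,2.8,0.5,4.1,0.3,3.6,0.2
Yemen,1.0,0.4,0.9,0.4,1.0,0.2,0.9,0.2
Zambia,1.4,0.1,1.2,0.1,2.3,0.2,2.0,0.2
Zimbabwe,0.7,0.1,0.6,0.1,1.0,0.1,0.9,0.1
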