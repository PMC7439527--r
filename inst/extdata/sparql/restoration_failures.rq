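PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>
PREFIX owl: <http://www.w3.org/2002/07/owl#>
PREFIX xsd: <http://www.w3.org/2001/XMLSchema#>
PREFIX ohd: <http://purl.example.org/ohd-mini/>
PREFIX ex: <http://purl.example.org/ohd-mini/practice/>
# Resin restorations paired with their earliest qualifying failure event:
# a later intracoronal restoration on the same tooth sharing a restored
# surface, or a crown / endodontic procedure / extraction of the same tooth.
# Encounter order comes from the materialized next_encounter chain
# (subsequent_encounter = next_encounter+). Minimal-date filtering is done by
# the aggregation.
SELECT ?restoration ?date (MIN(?later_date) AS ?failure_date)
WHERE {
  ?restoration rdf:type/rdfs:subClassOf* ohd:resin_filling_restoration ;
               ohd:occurrence_date ?date ;
               ohd:has_participant ?tooth .
  ?tooth rdf:type/rdfs:subClassOf* ohd:tooth .
  ?restoration ohd:next_encounter+ ?later .
  ?later ohd:occurrence_date ?later_date .
  {
    ?later rdf:type/rdfs:subClassOf* ohd:intracoronal_restoration_procedure .
    ?later ohd:has_participant ?tooth .
    ?restoration ohd:has_specified_input ?mat .
    ?mat ohd:is_dental_restoration_of ?surface .
    ?later ohd:has_specified_input ?mat2 .
    ?mat2 ohd:is_dental_restoration_of ?surface .
  } UNION {
    ?later rdf:type/rdfs:subClassOf* ohd:crown_restoration_procedure .
    ?later ohd:has_participant ?tooth .
  } UNION {
    ?later rdf:type/rdfs:subClassOf* ohd:endodontic_procedure .
    ?later ohd:has_participant ?tooth .
  } UNION {
    ?later rdf:type/rdfs:subClassOf* ohd:tooth_extraction_procedure .
    ?later ohd:has_participant ?tooth .
  }
}
GROUP BY ?restoration ?date
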